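# Tabular schemas for the two trial data sets, CSV round-trip IO, and the
# non-fatal wounding rate. One encounter row per shot-at animal; one
# post-mortem row per examined carcase.

encounter_columns <- function() {
  c(animal_id = "character", sortie_id = "integer", group_id = "integer",
    ammo = "character", ct_s = "numeric", tti_s = "numeric",
    tti_censored = "logical", shots_fired = "integer",
    outcome = "character", sex_age = "character")
}

postmortem_columns <- function() {
  c(animal_id = "character", wound_tracts = "integer",
    pellets_head = "integer", pellets_neck = "integer",
    pellets_thorax = "integer", pellets_abdomen = "integer",
    pellets_limbs = "integer", pellets_expected = "integer",
    body_mass_kg = "numeric", mass_censored = "logical",
    exam = "character")
}

pellet_zone_columns <- function() {
  paste0("pellets_", tolower(zone_names()))
}

fail_rows <- function(msg, ids) {
  ids <- unique(ids)
  shown <- paste(utils::head(ids, 10L), collapse = ", ")
  if (length(ids) > 10L) shown <- paste0(shown, ", ...")
  stop(msg, " [animal_id: ", shown, "]", call. = FALSE)
}

#' Validate an encounter table
#'
#' Checks the schema and the trial invariants: positive chase times, the
#' instant-insensibility rule (outcome `INSENSIBLE_LE_1S` implies an
#' uncensored time-to-insensibility of at most 1 s), absent
#' time-to-insensibility for animals that escaped, and exactly one
#' ammunition type per sortie (the randomised-block design assigns one
#' load per flight).
#'
#' @param records data.frame of encounter records.
#' @return `records`, invisibly, with canonical column order and types.
#' @export
validate_encounters <- function(records) {
  cols <- encounter_columns()
  missing_cols <- setdiff(names(cols), names(records))
  if (length(missing_cols) > 0L) {
    stop("encounter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, names(cols)]
  records$animal_id <- as.character(records$animal_id)
  records$ammo <- as.character(records$ammo)
  records$outcome <- as.character(records$outcome)
  records$sex_age <- as.character(records$sex_age)
  for (col in c("sortie_id", "group_id", "shots_fired")) {
    v <- records[[col]]
    if (any(is.na(v)) || any(v != as.integer(v))) {
      fail_rows(paste0("non-integer or missing ", col),
                records$animal_id[is.na(v) | v != as.integer(v)])
    }
    records[[col]] <- as.integer(v)
  }
  records$ct_s <- as.numeric(records$ct_s)
  records$tti_s <- as.numeric(records$tti_s)
  records$tti_censored <- as.logical(records$tti_censored)

  if (nrow(records) == 0L) return(invisible(records))

  if (anyDuplicated(records$animal_id)) {
    fail_rows("duplicated animal_id",
              records$animal_id[duplicated(records$animal_id)])
  }
  bad <- !(records$ammo %in% ammo_types())
  if (any(bad)) fail_rows("unknown ammo code", records$animal_id[bad])
  bad <- !(records$outcome %in% outcome_levels())
  if (any(bad)) fail_rows("unknown outcome code", records$animal_id[bad])
  bad <- !(records$sex_age %in% sex_age_levels())
  if (any(bad)) fail_rows("unknown sex_age code", records$animal_id[bad])
  bad <- is.na(records$ct_s) | records$ct_s <= 0
  if (any(bad)) fail_rows("ct_s must be > 0", records$animal_id[bad])
  bad <- records$sortie_id < 1L | records$group_id < 1L
  if (any(bad)) fail_rows("sortie_id and group_id must be >= 1",
                          records$animal_id[bad])
  bad <- records$shots_fired < 1L
  if (any(bad)) fail_rows("shots_fired must be >= 1", records$animal_id[bad])
  bad <- is.na(records$tti_censored)
  if (any(bad)) fail_rows("tti_censored must be true/false",
                          records$animal_id[bad])

  escaped <- records$outcome %in% c("WOUNDED_ESCAPED", "MISSED_ESCAPED")
  bad <- escaped & !is.na(records$tti_s)
  if (any(bad)) {
    fail_rows("tti_s must be absent for animals that escaped",
              records$animal_id[bad])
  }
  bad <- !escaped & (is.na(records$tti_s) | records$tti_s < 0)
  if (any(bad)) {
    fail_rows("tti_s must be present and >= 0 for killed animals",
              records$animal_id[bad])
  }
  instant <- records$outcome == "INSENSIBLE_LE_1S"
  bad <- instant & (records$tti_s > 1 | records$tti_censored)
  if (any(bad, na.rm = TRUE)) {
    fail_rows("INSENSIBLE_LE_1S requires uncensored tti_s <= 1",
              records$animal_id[which(bad)])
  }

  per_sortie <- tapply(records$ammo, records$sortie_id,
                       function(a) length(unique(a)))
  if (any(per_sortie > 1L)) {
    mixed <- names(per_sortie)[per_sortie > 1L]
    fail_rows("more than one ammo type within a sortie",
              records$animal_id[records$sortie_id %in% as.integer(mixed)])
  }
  invisible(records)
}

#' Validate a post-mortem table
#'
#' Checks that zone-wise pellet counts are consistent with the expected
#' count (shots fired times pellets per cartridge), and that every
#' ex-situ-examined shotgun carcase carries at least one pellet in the
#' thorax (the mandatory thorax shot of the shooting protocol).
#'
#' @param records data.frame of post-mortem records.
#' @param encounters optional encounter table; if supplied, every
#'   post-mortem `animal_id` must join to it.
#' @return `records`, invisibly.
#' @export
validate_postmortem <- function(records, encounters = NULL) {
  cols <- postmortem_columns()
  missing_cols <- setdiff(names(cols), names(records))
  if (length(missing_cols) > 0L) {
    stop("post-mortem table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, names(cols)]
  records$animal_id <- as.character(records$animal_id)
  records$exam <- as.character(records$exam)
  int_cols <- c("wound_tracts", pellet_zone_columns(), "pellets_expected")
  for (col in int_cols) records[[col]] <- as.integer(records[[col]])
  records$body_mass_kg <- as.numeric(records$body_mass_kg)
  records$mass_censored <- as.logical(records$mass_censored)

  if (nrow(records) == 0L) return(invisible(records))
  if (anyDuplicated(records$animal_id)) {
    fail_rows("duplicated animal_id",
              records$animal_id[duplicated(records$animal_id)])
  }
  bad <- !(records$exam %in% exam_levels())
  if (any(bad)) fail_rows("unknown exam code", records$animal_id[bad])
  for (col in int_cols) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0L
    if (any(bad)) fail_rows(paste0(col, " must be >= 0"),
                            records$animal_id[bad])
  }
  bad <- !is.na(records$body_mass_kg) & records$body_mass_kg <= 0
  if (any(bad)) fail_rows("body_mass_kg must be > 0", records$animal_id[bad])

  zones <- as.matrix(records[, pellet_zone_columns()])
  total <- rowSums(zones)
  bad <- !is.na(total) & !is.na(records$pellets_expected) &
    total > records$pellets_expected
  if (any(bad)) {
    fail_rows("sum of zone pellet counts exceeds pellets_expected",
              records$animal_id[bad])
  }

  if (!is.null(encounters)) {
    bad <- !(records$animal_id %in% encounters$animal_id)
    if (any(bad)) {
      fail_rows("post-mortem animal_id not present in encounter table",
                records$animal_id[bad])
    }
    enc <- encounters[match(records$animal_id, encounters$animal_id), ]
    shotgun_ex <- is_shotgun(enc$ammo) & records$exam == "EX_SITU" &
      !is.na(records$pellets_thorax)
    bad <- shotgun_ex & records$pellets_thorax < 1L
    if (any(bad)) {
      fail_rows("ex-situ shotgun carcase with no thorax pellet",
                records$animal_id[bad])
    }
  }
  invisible(records)
}

read_schema_csv <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- utils::read.csv(path, nrows = 1L, check.names = FALSE)
  if (!identical(names(header), names(cols)) && nrow(header) > 0L) {
    missing_cols <- setdiff(names(cols), names(header))
    extra <- setdiff(names(header), names(cols))
    if (length(missing_cols) > 0L || length(extra) > 0L) {
      stop("header mismatch in ", path,
           if (length(missing_cols)) paste0("; missing: ",
                                            paste(missing_cols, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  classes <- unname(cols)
  classes[classes == "logical"] <- "character"  # parse true/false ourselves
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = "")
  df <- df[, names(cols), drop = FALSE]
  for (i in seq_along(cols)) {
    col <- names(cols)[i]
    df[[col]] <- switch(
      cols[[i]],
      character = as.character(df[[col]]),
      integer = {
        v <- suppressWarnings(as.integer(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]]))) {
          stop("non-integer value in column ", col, " of ", path,
               " (row ", which(is.na(v) & !is.na(df[[col]]))[1L], ")",
               call. = FALSE)
        }
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]]))) {
          stop("non-numeric value in column ", col, " of ", path,
               " (row ", which(is.na(v) & !is.na(df[[col]]))[1L], ")",
               call. = FALSE)
        }
        v
      },
      logical = {
        raw <- df[[col]]
        v <- rep(NA, length(raw))
        v[raw %in% "true"] <- TRUE
        v[raw %in% "false"] <- FALSE
        if (any(is.na(v) & !is.na(raw))) {
          stop("column ", col, " of ", path,
               " must contain 'true'/'false' (row ",
               which(is.na(v) & !is.na(raw))[1L], ")", call. = FALSE)
        }
        v
      })
  }
  df
}

format_schema_csv <- function(df, cols) {
  out <- df[, names(cols), drop = FALSE]
  for (i in seq_along(cols)) {
    col <- names(cols)[i]
    v <- out[[col]]
    out[[col]] <- switch(
      cols[[i]],
      logical = ifelse(is.na(v), "", ifelse(v, "true", "false")),
      numeric = ifelse(is.na(v), "", format(v, trim = TRUE,
                                            scientific = FALSE)),
      ifelse(is.na(v), "", as.character(v)))
  }
  out
}

#' Read and write encounter tables
#'
#' `read_encounters()` parses and validates `encounters.csv`;
#' `write_encounters()` writes it back losslessly (booleans as
#' `true`/`false`, missing times as empty fields), so that a
#' read/write/read cycle reproduces every field.
#'
#' @param path CSV file path.
#' @return `read_encounters()`: a validated data.frame of encounter
#'   records. `write_encounters()`: `path`, invisibly.
#' @export
read_encounters <- function(path) {
  df <- read_schema_csv(path, encounter_columns())
  validate_encounters(df)
  df
}

#' @rdname read_encounters
#' @param records validated encounter data.frame.
#' @export
write_encounters <- function(records, path) {
  records <- validate_encounters(records)
  out <- format_schema_csv(records, encounter_columns())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_encounters
#' @export
read_postmortem <- function(path) {
  df <- read_schema_csv(path, postmortem_columns())
  validate_postmortem(df)
  df
}

#' @rdname read_encounters
#' @export
write_postmortem <- function(records, path) {
  records <- validate_postmortem(records)
  out <- format_schema_csv(records, postmortem_columns())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Non-fatal wounding rate
#'
#' The proportion of animals that were shot and hit but subsequently
#' escaped alive: `WOUNDED_ESCAPED` over all hit animals (outcomes other
#' than `MISSED_ESCAPED`). The worst welfare outcome of a culling
#' operation; in a trial where every shot-at animal is killed it is 0.
#'
#' @param records encounter data.frame.
#' @return Proportion in `[0, 1]`.
#' @export
nfwr <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no encounters", call. = FALSE)
  }
  hit <- records$outcome != "MISSED_ESCAPED"
  if (!any(hit)) stop("no hit animals in encounter table", call. = FALSE)
  sum(records$outcome == "WOUNDED_ESCAPED") / sum(hit)
}
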