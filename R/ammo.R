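#' Ammunition specifications
#'
#' The four ammunition arms of a helicopter-culling trial: a .308 rifle
#' firing a single 135-grain bullet, and three 12-gauge buckshot loads
#' containing 9 (00 Buck), 16 (1 Buck) or 27 (4 Buck) lead pellets per
#' cartridge.
#'
#' @return A data.frame with columns `ammo` and `pellets_per_cartridge`.
#' @export
#' @examples
#' ammo_spec()
ammo_spec <- function() {
  data.frame(
    ammo = ammo_types(),
    pellets_per_cartridge = unname(pellets_per_cartridge()),
    stringsAsFactors = FALSE
  )
}

#' @rdname ammo_spec
#' @export
ammo_types <- function() c("RIFLE_308", "BUCK_00", "BUCK_1", "BUCK_4")

#' @rdname ammo_spec
#' @export
pellets_per_cartridge <- function() {
  c(RIFLE_308 = 1L, BUCK_00 = 9L, BUCK_1 = 16L, BUCK_4 = 27L)
}

#' @rdname ammo_spec
#' @param ammo character vector of ammunition codes.
#' @export
is_shotgun <- function(ammo) {
  stopifnot(all(ammo %in% ammo_types()))
  ammo != "RIFLE_308"
}

# Anatomical zones scored on lateral radiographs.
zone_names <- function() c("HEAD", "NECK", "THORAX", "ABDOMEN", "LIMBS")

outcome_levels <- function() {
  c("INSENSIBLE_LE_1S", "INSENSIBLE_GT_1S", "WOUNDED_ESCAPED",
    "MISSED_ESCAPED")
}

sex_age_levels <- function() c("ADULT_M", "ADULT_F", "YEARLING", "FAWN")

exam_levels <- function() c("IN_SITU_ONLY", "EX_SITU")
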