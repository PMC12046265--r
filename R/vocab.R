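#' Canonicalize a symptom or region code
#'
#' Codes are lower-cased, trimmed, and internal whitespace / hyphens become
#' underscores, so `"Racing Heart"` and `"racing-heart"` both canonicalize to
#' `"racing_heart"`.
#'
#' @param x character vector of raw codes.
#' @return character vector of canonical codes.
#' @export
canonicalize_code <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[\\s-]+", "_", x, perl = TRUE)
}

# Default closed vocabularies. Qualities mix the "typical" anginal descriptors
# (dull, heavy, tight, pressure) with the sharp/burning qualities more often
# reported by women; associated symptoms are the canonical escalation list.
.default_qualities <- c("dull", "heavy", "tight", "pressure", "sharp", "burning")
.default_associated <- c(
  "shortness_of_breath", "palpitations", "racing_heart",
  "lightheaded", "faint", "dizzy"
)

#' Default front/back body-map regions
#'
#' The body map is a flat coded region list (no pixel geometry). The region
#' taxonomy is an informed reconstruction -- the published map is an image, not
#' a data artifact -- and always includes chest, jaw, shoulders, back, arms and
#' axillae. Shipped as `inst/extdata/body_regions.json`; this constructor is
#' the in-code fallback and the source the fixture was written from.
#'
#' @return data.frame with columns `code`, `side` (front|back), `label`.
#' @export
default_body_regions <- function() {
  front <- c(
    chest_center = "Center of chest", chest_left = "Left chest",
    chest_right = "Right chest", jaw_left = "Left jaw", jaw_right = "Right jaw",
    neck = "Neck / throat", shoulder_left = "Left shoulder",
    shoulder_right = "Right shoulder", arm_left = "Left arm",
    arm_right = "Right arm", axilla_left = "Left axilla (armpit)",
    axilla_right = "Right axilla (armpit)", abdomen_upper = "Upper abdomen"
  )
  back <- c(
    back_upper = "Upper back", back_mid = "Mid back (between shoulder blades)",
    back_lower = "Lower back", shoulder_blade_left = "Left shoulder blade",
    shoulder_blade_right = "Right shoulder blade"
  )
  data.frame(
    code = c(names(front), names(back)),
    side = c(rep("front", length(front)), rep("back", length(back))),
    label = unname(c(front, back)),
    stringsAsFactors = FALSE
  )
}

#' Construct the closed triage vocabulary
#'
#' Vocabularies are closed per run: any code outside them is a validation
#' error, never a warning, because a triage rule that silently drops an
#' unrecognized symptom token is unsafe.
#'
#' @param qualities character vector of pain-quality codes.
#' @param associated character vector of associated-symptom codes.
#' @param regions data.frame of body regions (`code`, `side`, `label`).
#' @return object of class `triage_vocab`.
#' @export
triage_vocab <- function(qualities = .default_qualities,
                         associated = .default_associated,
                         regions = default_body_regions()) {
  qualities <- canonicalize_code(qualities)
  associated <- canonicalize_code(associated)
  stopifnot(
    is.data.frame(regions),
    all(c("code", "side", "label") %in% names(regions))
  )
  regions$code <- canonicalize_code(regions$code)
  if (anyDuplicated(qualities)) stop("duplicate quality codes", call. = FALSE)
  if (anyDuplicated(associated)) stop("duplicate associated-symptom codes", call. = FALSE)
  if (anyDuplicated(regions$code)) stop("duplicate body-region codes", call. = FALSE)
  if (!all(regions$side %in% c("front", "back"))) {
    stop("region side must be 'front' or 'back'", call. = FALSE)
  }
  required <- c("chest", "jaw", "shoulder", "back", "arm", "axilla")
  present <- vapply(required, function(p) any(startsWith(regions$code, p)), logical(1))
  if (!all(present)) {
    stop(
      "body map must include regions for: ",
      paste(required[!present], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(qualities = qualities, associated = associated, regions = regions),
    class = "triage_vocab"
  )
}

#' Load a vocabulary/body-map configuration from JSON
#'
#' The config file holds three keys: `qualities` and `associated` (arrays of
#' codes) and `regions` (array of `{code, side, label}` objects). Missing keys
#' fall back to the package defaults.
#'
#' @param path path to a JSON config file, or `NULL` for the bundled default.
#' @return `triage_vocab`.
#' @export
load_vocab <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocab.json", package = "hearttriage")
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  triage_vocab(
    qualities = if (!is.null(cfg$qualities)) cfg$qualities else .default_qualities,
    associated = if (!is.null(cfg$associated)) cfg$associated else .default_associated,
    regions = if (!is.null(cfg$regions)) as.data.frame(cfg$regions) else default_body_regions()
  )
}

# Validate a set of codes against one vocabulary dimension; returns the
# canonical, de-duplicated, sorted set. Sorting makes serialization canonical.
check_codes <- function(codes, allowed, what) {
  if (is.null(codes) || length(codes) == 0) return(character(0))
  codes <- canonicalize_code(codes)
  bad <- setdiff(codes, allowed)
  if (length(bad) > 0) {
    stop(
      "unknown ", what, " code(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  sort(unique(codes))
}

#' @export
print.triage_vocab <- function(x, ...) {
  cat("Triage vocabulary\n")
  cat("  qualities: ", paste(x$qualities, collapse = ", "), "\n", sep = "")
  cat("  associated:", paste(x$associated, collapse = ", "), "\n")
  cat("  regions:   ", nrow(x$regions), " coded body-map regions\n", sep = "")
  invisible(x)
}
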