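#' Famine exposure groups from birth year
#'
#' Deterministic classification of participants into exposure groups for the
#' 1959-1961 Great Chinese Famine natural experiment, by calendar birth year
#' only.  Codes: `E1` (born 1959; exposed in utero and the first two
#' postnatal years, i.e. the first 1000 days of life), `E2` (1960; in utero
#' and first postnatal year), `E3` (1961; in utero only), `NE2` (1962-1964;
#' the no-exposed control/reference group), `NE1` (born after 1964;
#' no-exposed), `E4` (1956-1958; infancy and toddler), `E5` (1953-1955;
#' preschooler), `E6` (1947-1952; school-aged child), `E7` (1942-1946;
#' adolescent), `E8` (born before 1942; adult).  The ten rules partition all
#' integer birth years.
#'
#' @param birth_year integer vector of birth years (no missing values;
#'   samples without a birth year are excluded upstream).
#' @return a factor with levels `NE1, NE2, E1, ..., E8`.
#' @examples
#' classify_exposure(c(1959, 1963, 1941, 1980))
#' @export
classify_exposure <- function(birth_year) {
  if (any(is.na(birth_year)))
    stop("missing birth year: classification refused (exclude such samples upstream)")
  if (any(birth_year != round(birth_year)))
    stop("`birth_year` must be integer calendar years")
  y <- as.integer(birth_year)
  code <- ifelse(y == 1959L, "E1",
          ifelse(y == 1960L, "E2",
          ifelse(y == 1961L, "E3",
          ifelse(y >= 1962L & y <= 1964L, "NE2",
          ifelse(y >  1964L, "NE1",
          ifelse(y >= 1956L, "E4",
          ifelse(y >= 1953L, "E5",
          ifelse(y >= 1947L, "E6",
          ifelse(y >= 1942L, "E7", "E8")))))))))
  factor(code, levels = exposure_levels())
}

#' @rdname classify_exposure
#' @export
exposure_levels <- function() c("NE1", "NE2", paste0("E", 1:8))

#' Human-readable labels for the exposure groups
#' @return named character vector, code -> label.
#' @export
exposure_labels <- function() c(
  NE1 = "no-exposed (born after 1964)",
  NE2 = "no-exposed control (born 1962-1964)",
  E1 = "first 1000 days exposed (born 1959)",
  E2 = "in utero + first year exposed (born 1960)",
  E3 = "in utero exposed (born 1961)",
  E4 = "infancy and toddler exposed (born 1956-1958)",
  E5 = "preschooler exposed (born 1953-1955)",
  E6 = "school-aged child exposed (born 1947-1952)",
  E7 = "adolescent exposed (born 1942-1946)",
  E8 = "adult exposed (born before 1942)")

#' Sensitivity regroupings of the exposure assignment
#'
#' Three regrouping schemes used in sensitivity analyses:
#' `post1978_reference` moves participants born after 1978 into a new
#' reference group `REF_post1978` (requires `birth_year`);
#' `control_plus_E4_reference` merges the control group (1962-1964) with the
#' infancy/toddler group (1956-1958) into `REF_NE2_E4`, balancing age between
#' reference and the in-utero groups; `utero_combined` merges E1-E3 into a
#' single `E_utero` group.  All other assignments are unchanged.
#'
#' @param groups factor from [classify_exposure()].
#' @param scheme one of `"post1978_reference"`, `"control_plus_E4_reference"`,
#'   `"utero_combined"`.
#' @param birth_year integer vector, required for `post1978_reference`.
#' @return a factor of remapped group labels, with the scheme's reference
#'   group name in attribute `"reference"`.
#' @export
regroup_exposure <- function(groups,
                             scheme = c("post1978_reference",
                                        "control_plus_E4_reference",
                                        "utero_combined"),
                             birth_year = NULL) {
  scheme <- match.arg(scheme)
  g <- as.character(groups)
  ref <- "NE2"
  if (scheme == "post1978_reference") {
    if (is.null(birth_year))
      stop("`birth_year` is required for scheme post1978_reference")
    if (length(birth_year) != length(g))
      stop("`birth_year` and `groups` lengths differ")
    g[birth_year > 1978L] <- "REF_post1978"
    ref <- "REF_post1978"
  } else if (scheme == "control_plus_E4_reference") {
    g[g %in% c("NE2", "E4")] <- "REF_NE2_E4"
    ref <- "REF_NE2_E4"
  } else if (scheme == "utero_combined") {
    g[g %in% c("E1", "E2", "E3")] <- "E_utero"
  }
  lev <- unique(c(ref, setdiff(c(exposure_levels(),
                                 "REF_post1978", "REF_NE2_E4", "E_utero"), ref)))
  out <- factor(g, levels = intersect(lev, unique(g)))
  attr(out, "reference") <- ref
  out
}

#' Tabulate exposure groups with percentages
#'
#' Counts and percentages of each exposure group among a set of
#' participants, the standard first table of a famine cohort analysis.
#'
#' @param birth_year integer vector of birth years.
#' @param digits decimal places for the percentage (default 1, matching the
#'   usual presentation).
#' @return data frame with columns `group`, `n`, `pct`.
#' @export
exposure_table <- function(birth_year, digits = 1) {
  g <- classify_exposure(birth_year)
  n <- as.integer(base::table(g))
  data.frame(group = exposure_levels(), n = n,
             pct = round(100 * n / length(g), digits),
             stringsAsFactors = FALSE)
}
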