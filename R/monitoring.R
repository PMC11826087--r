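#' Size-class census columns
#'
#' Column names used for the ten size classes of the longitudinal census:
#' I (cotyledons only), II (longest leaf < 1 cm), III (1 to < 4 cm),
#' IV (4 to < 8 cm), V (8 to < 12 cm), VI (>= 12 cm), VII (bolting),
#' VIII (inflorescences formed), IX (fully flowering), X (seed set).
#'
#' @return character vector `class_I` ... `class_X`.
#' @export
sizeClassColumns <- function() {
  paste0("class_", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                     "IX", "X"))
}

.needClasses <- function(rec, classes = sizeClassColumns()) {
  miss <- setdiff(classes, colnames(rec))
  if (length(miss))
    stop("monitoring record lacks columns: ", paste(miss, collapse = ", "))
  bad <- vapply(classes, function(cl) any(rec[[cl]] < 0, na.rm = TRUE),
                logical(1))
  if (any(bad))
    stop("negative counts in: ", paste(classes[bad], collapse = ", "))
  invisible(rec)
}

.sumClasses <- function(rec, which) {
  cols <- sizeClassColumns()[which]
  rowSums(as.matrix(rec[, cols, drop = FALSE]))
}

#' Size-class ratio (relative growth)
#'
#' Log ratio of developed vegetative individuals (classes II-VI) to
#' cotyledon-stage seedlings (class I), with +1 offsets so the statistic is
#' finite for every record including the all-zero one:
#' \deqn{\ln\frac{N_{II}+N_{III}+N_{IV}+N_V+N_{VI}+1}{N_I+1}.}
#'
#' @param rec data.frame with the [sizeClassColumns()] count columns (one row
#'   per unit-week record); vectorised over rows.
#' @return numeric vector.
#' @examples
#' rec <- data.frame(class_I = 4, class_II = 3, class_III = 3, class_IV = 3,
#'                   class_V = 0, class_VI = 0, class_VII = 0,
#'                   class_VIII = 0, class_IX = 0, class_X = 0)
#' sizeClassRatio(rec)   # ln(10/5)
#' @export
sizeClassRatio <- function(rec) {
  .needClasses(rec)
  log((.sumClasses(rec, 2:6) + 1) / (.sumClasses(rec, 1) + 1))
}

#' Rosette-size ratio (8 cm threshold)
#'
#' Same log-ratio construction, splitting the vegetative classes at the 8 cm
#' rosette threshold: classes V-VI (longest leaf >= 8 cm) against classes
#' I-IV.  Bolting classes VII-X are no longer rosettes and enter neither
#' side.
#'
#' @inheritParams sizeClassRatio
#' @return numeric vector.
#' @export
rosetteSizeRatio <- function(rec) {
  .needClasses(rec)
  log((.sumClasses(rec, 5:6) + 1) / (.sumClasses(rec, 1:4) + 1))
}

#' Life-stage ratio (generative vs. vegetative)
#'
#' Log ratio of generative individuals (bolting/flowering classes VII-X) to
#' vegetative individuals (classes I-VI), +1 offsets.
#'
#' @inheritParams sizeClassRatio
#' @return numeric vector.
#' @export
lifeStageRatio <- function(rec) {
  .needClasses(rec)
  log((.sumClasses(rec, 7:10) + 1) / (.sumClasses(rec, 1:6) + 1))
}

#' Total individuals per record
#'
#' Sum of all ten size classes; `vegetative_only = TRUE` restricts to
#' classes I-VI (the individuals counted as vegetative rosettes).
#'
#' @inheritParams sizeClassRatio
#' @param vegetative_only sum only classes I-VI.
#' @return integer vector.
#' @export
totalIndividuals <- function(rec, vegetative_only = FALSE) {
  .needClasses(rec)
  as.integer(.sumClasses(rec, if (vegetative_only) 1:6 else 1:10))
}

#' Read a monitoring table
#'
#' Wide format: `unit_id`, `week`, then the ten [sizeClassColumns()].
#' Long format (`format = "long"`): `unit_id`, `week`, `class`, `count`,
#' where `class` is one of I...X; pivoted to wide on read (absent classes
#' become 0).  Strict validation with row-level messages: non-negative
#' integer counts, week >= 1, no duplicate unit-week(-class) rows.
#'
#' @param path CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @return wide-format data.frame.
#' @export
readMonitoring <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("unit_id", "week", "class", "count")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stop("long monitoring table lacks columns: ",
           paste(miss, collapse = ", "))
    roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
    bad <- which(!tab$class %in% roman)
    if (length(bad))
      stop("unknown size class at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    key <- paste(tab$unit_id, tab$week, tab$class)
    if (anyDuplicated(key))
      stop("duplicate unit/week/class at row(s): ",
           paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
    wide <- expand.grid(unit_id = unique(tab$unit_id),
                        week = sort(unique(tab$week)),
                        stringsAsFactors = FALSE)
    for (i in seq_along(roman)) {
      cl <- roman[i]
      sub <- tab[tab$class == cl, c("unit_id", "week", "count")]
      colnames(sub)[3] <- paste0("class_", cl)
      wide <- merge(wide, sub, by = c("unit_id", "week"), all.x = TRUE)
    }
    cls <- sizeClassColumns()
    wide[cls][is.na(wide[cls])] <- 0L
    tab <- wide
  }
  need <- c("unit_id", "week", sizeClassColumns())
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("monitoring table lacks columns: ", paste(miss, collapse = ", "))
  for (cl in sizeClassColumns()) {
    bad <- which(is.na(tab[[cl]]) | tab[[cl]] < 0 |
                   tab[[cl]] != round(tab[[cl]]))
    if (length(bad))
      stop("column ", cl, ": non-negative integer counts required at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(tab$week) | tab$week < 1)
  if (length(bad))
    stop("week must be >= 1 at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(tab$unit_id, tab$week)
  if (anyDuplicated(key))
    stop("duplicate unit/week rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  tab[order(tab$unit_id, tab$week), , drop = FALSE]
}

#' Read a harvest table
#'
#' Columns `unit_id`, `vegetative_biomass_g`, `reproductive_biomass_g`
#' (grams dry weight, >= 0); `total_biomass_g` is derived (or checked, when
#' present, to equal the sum within 1e-9).
#'
#' @param path CSV path.
#' @param exclude character vector of `unit_id`s to drop explicitly (e.g.
#'   damaged samples); exclusions are recorded in an attribute, never silent.
#' @return data.frame with an `excluded` attribute.
#' @export
readHarvest <- function(path, exclude = character()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "vegetative_biomass_g", "reproductive_biomass_g")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("harvest table lacks columns: ", paste(miss, collapse = ", "))
  for (cl in need[-1]) {
    bad <- which(is.na(tab[[cl]]) | tab[[cl]] < 0)
    if (length(bad))
      stop("column ", cl, ": non-negative values required at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  tot <- tab$vegetative_biomass_g + tab$reproductive_biomass_g
  if ("total_biomass_g" %in% colnames(tab)) {
    if (any(abs(tab$total_biomass_g - tot) > 1e-9))
      stop("total_biomass_g must equal vegetative + reproductive (1e-9)")
  } else tab$total_biomass_g <- tot
  dropped <- intersect(exclude, tab$unit_id)
  tab <- tab[!tab$unit_id %in% exclude, , drop = FALSE]
  attr(tab, "excluded") <- dropped
  tab
}
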