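#' Transwell invasion field counts
#'
#' Invading cells are counted in a few imaged fields at the bottom of a
#' Boyden chamber; total invader numbers are extrapolated from the imaged
#' fraction of the membrane.
#'
#' @param counts non-negative integer counts of invading cells per imaged
#'   field.
#' @param frame_side_mm side length of the (square) imaged field, mm.
#' @param total_area_cm2 membrane area, cm^2.
#' @param seeded_n number of cells seeded.
#' @return object of class `field_counts`.
#' @examples
#' fc <- field_counts(c(100, 100, 100, 100, 100), seeded_n = 45000)
#' area_factor(fc)               # ~21.54
#' invasiveness_from_counts(fc)  # ~0.0479
#' @export
field_counts <- function(counts, frame_side_mm = 1.18, total_area_cm2 = 0.3,
                         seeded_n) {
  stopifnot(is.numeric(counts), length(counts) >= 1L, all(counts >= 0),
            all(counts == round(counts)),
            frame_side_mm > 0, total_area_cm2 > 0, seeded_n > 0)
  structure(list(counts = as.numeric(counts),
                 frame_side_mm = frame_side_mm,
                 total_area_cm2 = total_area_cm2,
                 seeded_n = seeded_n),
            class = "field_counts")
}

#' Area extrapolation factor for a transwell membrane
#'
#' Ratio of the total membrane area to one imaged field:
#' `total_area_cm2 * 100 / frame_side_mm^2` (1 cm^2 = 100 mm^2). With the
#' default 1.18 mm field on a 0.3 cm^2 membrane the factor is 21.55.
#'
#' @param fc a [field_counts()].
#' @return dimensionless factor.
#' @export
area_factor <- function(fc) {
  stopifnot(inherits(fc, "field_counts"))
  fc$total_area_cm2 * 100 / fc$frame_side_mm^2
}

#' Population invasiveness from field counts
#'
#' Mean field count, scaled by the area factor to the whole membrane,
#' divided by the number of seeded cells. Values above 1 (possible under
#' counting noise) are preserved and flagged via attribute
#' `over_unity = TRUE` rather than clamped.
#'
#' @param fc a [field_counts()].
#' @return invasiveness fraction.
#' @export
invasiveness_from_counts <- function(fc) {
  stopifnot(inherits(fc, "field_counts"))
  v <- mean(fc$counts) * area_factor(fc) / fc$seeded_n
  if (v > 1) attr(v, "over_unity") <- TRUE
  v
}

#' alamarBlue reduction score
#'
#' Viable-cell metabolic readout from dual-wavelength absorbance:
#' `S = O2 * A570 - O1 * A600`, where O1 and O2 are the molar extinction
#' coefficients of the oxidized reagent at 570 and 600 nm. The
#' coefficients are reagent-lot properties and must be supplied; no
#' defaults are hard-coded.
#'
#' @param a570,a600 blank-subtracted absorbances at 570 and 600 nm.
#' @param o1,o2 molar extinction coefficients at 570 and 600 nm (1/M/cm),
#'   > 0.
#' @return score S (sign-preserving).
#' @export
alamarblue_score <- function(a570, a600, o1, o2) {
  stopifnot(is.numeric(a570), is.numeric(a600),
            is.numeric(o1), length(o1) == 1L, o1 > 0,
            is.numeric(o2), length(o2) == 1L, o2 > 0)
  o2 * a570 - o1 * a600
}

#' Relative proliferation between condition and control
#'
#' Fold change between the average reduction scores of induced and control
#' wells.
#'
#' @param s_condition scores of the condition wells.
#' @param s_control scores of the control wells.
#' @return fold change (mean condition / mean control).
#' @export
relative_proliferation <- function(s_condition, s_control) {
  stopifnot(is.numeric(s_condition), is.numeric(s_control))
  m <- mean(s_control)
  if (m == 0) stop("control score mean is zero")
  mean(s_condition) / m
}

#' Population doubling time from relative proliferation fold changes
#'
#' `Td = (t2 - t1) * ln(2) / ln(f2 / f1)`. A shrinking population
#' (f2 < f1) yields a negative value, returned with attribute
#' `shrinking = TRUE`.
#'
#' @param t1,t2 measurement times (hours), `t2 > t1`.
#' @param f1,f2 average relative proliferation fold changes at `t1`, `t2`;
#'   positive, `f2 != f1`.
#' @return doubling time in hours.
#' @examples
#' doubling_time(0, 48, 1, 2)  # 48 h
#' @export
doubling_time <- function(t1, t2, f1, f2) {
  if (t2 <= t1) stop("t2 must exceed t1")
  if (f1 <= 0 || f2 <= 0) stop("fold changes must be positive")
  if (f2 == f1) stop("no growth: fold change unchanged, doubling time undefined")
  td <- (t2 - t1) * log(2) / log(f2 / f1)
  if (td < 0) attr(td, "shrinking") <- TRUE
  td
}

#' Read a per-condition counts TSV and compute invasiveness
#'
#' Expects columns `condition`, `field_index`, `count`, `seeded_n` (one row
#' per imaged field); frame and membrane geometry are shared across rows.
#'
#' @param path TSV path.
#' @param frame_side_mm,total_area_cm2 imaging geometry (defaults: 1.18 mm
#'   field, 0.3 cm^2 membrane).
#' @param out optional output TSV path for the per-condition invasiveness
#'   table.
#' @return data.frame with columns `condition`, `n_fields`, `mean_count`,
#'   `invasiveness`.
#' @export
invasiveness_table <- function(path, frame_side_mm = 1.18,
                               total_area_cm2 = 0.3, out = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("condition", "field_index", "count", "seeded_n")
  if (!all(need %in% names(df))) {
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  }
  res <- do.call(rbind, lapply(split(df, df$condition), function(g) {
    fc <- field_counts(g$count, frame_side_mm, total_area_cm2,
                       seeded_n = g$seeded_n[1])
    data.frame(condition = g$condition[1], n_fields = nrow(g),
               mean_count = mean(g$count),
               invasiveness = as.numeric(invasiveness_from_counts(fc)))
  }))
  rownames(res) <- NULL
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}
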