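#' Tissue-class counts of one mammogram
#'
#' Minimal container for per-mammogram window counts, used both by the real
#' pipeline (from a class map) and by the metrics-level cohort simulator.
#'
#' @param fatty,disrupted,dense,rejected non-negative window counts.
#' @return List of class `class_counts`.
#' @export
class_counts <- function(fatty, disrupted, dense, rejected = 0L) {
  for (v in c(fatty, disrupted, dense, rejected))
    if (!is_count(v)) stop_bad_arg("counts must be non-negative integers")
  structure(list(fatty = as.integer(fatty), disrupted = as.integer(disrupted),
                 dense = as.integer(dense), rejected = as.integer(rejected)),
            class = "class_counts")
}

as_class_counts <- function(x) {
  if (inherits(x, "class_counts")) return(x)
  if (inherits(x, "mammogram_analysis")) x <- x$class_map
  if (is.matrix(x) || is.character(x) || is.factor(x)) {
    v <- as.character(x)
    return(class_counts(sum(v == "fatty", na.rm = TRUE),
                        sum(v == "disrupted", na.rm = TRUE),
                        sum(v == "dense", na.rm = TRUE),
                        sum(v == "rejected", na.rm = TRUE)))
  }
  stop_bad_arg("cannot interpret %s as tissue-class counts", class(x)[1])
}

#' Per-mammogram composition metrics
#'
#' Computes the percentage of fatty (blue, %B), disrupted (yellow, %Y) and
#' dense (red, %R) windows, and the combination score %Y/%B.  By default the
#' denominator is the number of accepted (non-rejected) windows; set
#' `include_rejected_in_denominator` to count gray windows too.
#'
#' @param map a tissue-class map (`mammogram_analysis`, class-map matrix, or
#'   [class_counts]).
#' @param include_rejected_in_denominator logical.
#' @return List of class `mammogram_metrics`: `pct_blue`, `pct_yellow`,
#'   `pct_red`, `yb_ratio` (NA with a flag when %B = 0), `n_accepted`,
#'   `n_rejected`.
#' @examples
#' compute_metrics(class_counts(10, 10, 20, 5))
#' @export
compute_metrics <- function(map, include_rejected_in_denominator = FALSE) {
  cc <- as_class_counts(map)
  acc <- cc$fatty + cc$disrupted + cc$dense
  if (acc == 0L) stop_bad_arg("no accepted windows: metrics undefined")
  den <- if (include_rejected_in_denominator) acc + cc$rejected else acc
  pb <- 100 * cc$fatty / den
  py <- 100 * cc$disrupted / den
  pr <- 100 * cc$dense / den
  structure(list(pct_blue = pb, pct_yellow = py, pct_red = pr,
                 yb_ratio = if (pb > 0) py / pb else NA_real_,
                 yb_defined = pb > 0,
                 n_accepted = acc, n_rejected = cc$rejected),
            class = "mammogram_metrics")
}

#' YB Factor: bilateral asymmetry of tissue disruption
#'
#' \deqn{\mathrm{YB\ Factor} = \frac{\%Y_{tumor}/\%B_{tumor}}
#' {\%Y_{opposite}/\%B_{opposite}}}
#' A value near 1 indicates similar disruption-to-fat balance in the two
#' breasts; values above 1 quantify excess disruption on the tumor side.
#'
#' @param tumor,opposite `mammogram_metrics` of the tumorous and
#'   contralateral breast.
#' @return Single positive number.
#' @examples
#' a <- compute_metrics(class_counts(10, 20, 20))
#' b <- compute_metrics(class_counts(10, 10, 20))
#' yb_factor(a, b)  # 2
#' @export
yb_factor <- function(tumor, opposite) {
  if (!isTRUE(tumor$yb_defined))
    stop_bad_arg("%%Y/%%B undefined for the tumor breast (%%B = 0)")
  if (!isTRUE(opposite$yb_defined))
    stop_bad_arg("%%Y/%%B undefined for the opposite breast (%%B = 0)")
  if (opposite$yb_ratio <= 0)
    stop_bad_arg("opposite-breast %%Y/%%B must be positive")
  tumor$yb_ratio / opposite$yb_ratio
}

#' Assemble a per-patient record
#'
#' @param patient_id identifier.
#' @param group diagnosis group label.
#' @param tumor_side `"left"` or `"right"`.
#' @param tumor,opposite `mammogram_metrics` per breast (opposite may be
#'   `NULL` for a partial record).
#' @return List of class `patient_record` including `yb_factor` (NA when
#'   undefined, with `yb_reason`).
#' @export
patient_record <- function(patient_id, group, tumor_side, tumor, opposite = NULL) {
  yb <- NA_real_; reason <- NA_character_
  if (is.null(opposite)) {
    reason <- "missing-opposite"
  } else if (!isTRUE(tumor$yb_defined) || !isTRUE(opposite$yb_defined) ||
             opposite$yb_ratio <= 0) {
    reason <- "undefined-ratio"
  } else {
    yb <- yb_factor(tumor, opposite)
  }
  structure(list(patient_id = patient_id, group = group, tumor_side = tumor_side,
                 tumor = tumor, opposite = opposite,
                 yb_factor = yb, yb_reason = reason),
            class = "patient_record")
}

#' Flatten patient records into a per-breast / per-patient table
#'
#' @param records list of `patient_record`s.
#' @return `data.frame` with one row per patient: group, per-breast %B/%Y/%R
#'   and %Y/%B, window counts, and the YB Factor.
#' @export
patient_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    row <- data.frame(patient_id = r$patient_id, group = r$group,
                      tumor_side = r$tumor_side, yb_factor = r$yb_factor,
                      yb_reason = r$yb_reason, stringsAsFactors = FALSE)
    for (side in c("tumor", "opposite")) {
      m <- r[[side]]
      pre <- function(x) paste0(side, "_", x)
      if (is.null(m)) {
        row[[pre("pct_blue")]] <- row[[pre("pct_yellow")]] <- row[[pre("pct_red")]] <-
          row[[pre("yb_ratio")]] <- NA_real_
        row[[pre("n_accepted")]] <- row[[pre("n_rejected")]] <- NA_integer_
      } else {
        row[[pre("pct_blue")]] <- m$pct_blue
        row[[pre("pct_yellow")]] <- m$pct_yellow
        row[[pre("pct_red")]] <- m$pct_red
        row[[pre("yb_ratio")]] <- m$yb_ratio
        row[[pre("n_accepted")]] <- m$n_accepted
        row[[pre("n_rejected")]] <- m$n_rejected
      }
    }
    row
  }))
}
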