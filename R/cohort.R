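#' Study-design group sizes
#'
#' Default per-group patient counts of the emulated study population:
#' 43 ILC, 38 IDC (1 grade-1, 27 grade-2, 10 grade-3), 12 fibroadenoma and
#' 11 fibrocystic mastopathy, i.e. 81 cancer and 23 benign patients.
#'
#' @return Named integer vector.
#' @export
table1_group_sizes <- function() {
  c(ILC = 43L, IDC1 = 1L, IDC2 = 27L, IDC3 = 10L, fib_a = 12L, fib_m = 11L)
}

cancer_groups <- function() c("ILC", "IDC1", "IDC2", "IDC3")

#' Synthetic cohort specification
#'
#' Describes a two-breast cohort at the level of tissue composition.  Every
#' patient draws baseline class fractions (logistic-normal jitter around the
#' cohort baseline); each breast jitters again independently, so benign
#' patients have statistically exchangeable breasts.  For cancer patients
#' the tumor-side disrupted fraction is increased by `cancer_effect` with an
#' equal reduction of the fatty fraction.
#'
#' @param n_per_group named counts per group label (subset of
#'   `ILC, IDC1, IDC2, IDC3, fib_a, fib_m`); defaults to [table1_group_sizes].
#' @param baseline_fractions fatty / disrupted / dense fractions of the
#'   analyzed breast area (must be positive, sum <= 1; the remainder is the
#'   rejected-window rate).
#' @param cancer_effect additive shift of the disrupted fraction on the
#'   tumor side of cancer patients (benign groups always get zero).
#' @param sd_patient,sd_breast logistic-normal jitter (log-odds scale)
#'   between patients and between breasts.
#' @param n_windows_range range of analyzed windows per breast.
#' @param reject_rate expected fraction of rejected (gray) windows.
#' @param seed integer master seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = table1_group_sizes(),
                        baseline_fractions = c(fatty = 0.55, disrupted = 0.10,
                                               dense = 0.35),
                        cancer_effect = 0.15,
                        sd_patient = 0.30, sd_breast = 0.25,
                        n_windows_range = c(1200L, 1800L),
                        reject_rate = 0.05,
                        seed = 1L) {
  if (any(baseline_fractions <= 0) || sum(baseline_fractions) > 1 + 1e-9)
    stop_bad_arg("baseline fractions must be positive and sum to at most 1")
  bad <- setdiff(names(n_per_group), c("ILC", "IDC1", "IDC2", "IDC3", "fib_a", "fib_m"))
  if (length(bad)) stop_bad_arg("unknown group label(s): %s", paste(bad, collapse = ", "))
  if (any(n_per_group < 0)) stop_bad_arg("group counts must be non-negative")
  if (cancer_effect < 0) stop_bad_arg("cancer_effect must be non-negative")
  structure(list(n_per_group = n_per_group,
                 baseline_fractions = baseline_fractions,
                 cancer_effect = cancer_effect,
                 sd_patient = sd_patient, sd_breast = sd_breast,
                 n_windows_range = as.integer(n_windows_range),
                 reject_rate = reject_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

## softmax over log-fractions + jitter
jitter_fractions <- function(base, eps) {
  z <- log(base) + eps
  exp(z) / sum(exp(z))
}

simulate_breast_counts <- function(frac, n_windows, reject_rate, shift = 0) {
  f <- frac
  if (shift != 0) {
    f["disrupted"] <- f["disrupted"] + shift
    f["fatty"] <- f["fatty"] - shift
    f <- pmax(f, 0.01)
    f <- f / sum(f)
  }
  n_rej <- stats::rbinom(1L, n_windows, reject_rate)
  cnt <- stats::rmultinom(1L, n_windows - n_rej, f)[, 1]
  class_counts(cnt["fatty"], cnt["disrupted"], cnt["dense"], n_rej)
}

#' Generate a synthetic two-breast cohort
#'
#' `level = "metrics"` (default) simulates per-breast window counts directly
#' and returns the per-patient metrics table - the statistical structure of
#' the study without the cost of image synthesis.  `level = "images"`
#' additionally builds a phantom mammogram pair per patient (band-layout
#' regions matching the target fractions), for small cohorts only.
#'
#' Per-patient seeds are derived deterministically from `spec$seed`, so the
#' same specification always yields the same cohort.
#'
#' @param spec a [cohort_spec].
#' @param level `"metrics"` or `"images"`.
#' @param image_side phantom side when `level = "images"`.
#' @return For `"metrics"`: a `data.frame` as from [patient_table].  For
#'   `"images"`: a list of patient entries, each with `patient_id`, `group`,
#'   `tumor_side` and phantom `tumor` / `opposite` entries (image, mask,
#'   truth) plus the same metrics row.
#' @export
generate_cohort <- function(spec = cohort_spec(), level = c("metrics", "images"),
                            image_side = 520L) {
  level <- match.arg(level)
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  records <- vector("list", length(groups))
  images <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    is_cancer <- g %in% cancer_groups()
    pid <- sprintf("P%03d", i)
    with_seed(derive_seed(spec$seed, i), {
      base <- jitter_fractions(spec$baseline_fractions,
                               stats::rnorm(3, 0, spec$sd_patient))
      tumor_side <- sample(c("left", "right"), 1L)
      mk_breast <- function(shift) {
        f <- jitter_fractions(base, stats::rnorm(3, 0, spec$sd_breast))
        names(f) <- names(spec$baseline_fractions)
        n_win <- sample(spec$n_windows_range[1]:spec$n_windows_range[2], 1L)
        simulate_breast_counts(f, n_win, spec$reject_rate,
                               shift = if (is_cancer) shift else 0)
      }
      tum <- compute_metrics(mk_breast(spec$cancer_effect))
      opp <- compute_metrics(mk_breast(0))
      records[[i]] <- patient_record(pid, g, tumor_side, tum, opp)
      if (level == "images") {
        frac_of <- function(m) c(m$pct_blue, m$pct_yellow, m$pct_red) / 100
        images[[i]] <- list(
          patient_id = pid, group = g, tumor_side = tumor_side,
          tumor = banded_phantom(image_side, frac_of(tum),
                                 derive_seed(spec$seed, i, 1L)),
          opposite = banded_phantom(image_side, frac_of(opp),
                                    derive_seed(spec$seed, i, 2L)))
      }
    })
  }
  tab <- patient_table(records)
  if (level == "metrics") return(tab)
  for (i in seq_along(images)) images[[i]]$metrics <- tab[i, ]
  images
}

## phantom whose horizontal band areas match the target class fractions
banded_phantom <- function(side, fractions, seed) {
  br <- cumsum(c(0, fractions))
  H_of <- c(0.30, 0.50, 0.65)     # fatty, disrupted, dense
  regions <- list()
  for (j in 1:3) {
    if (fractions[j] <= 0) next
    regions[[length(regions) + 1L]] <-
      phantom_region(H_of[j], amplitude = 1, shape = "band",
                     from = br[j], to = br[j + 1])
  }
  spec <- phantom_spec(image_side = side, mask_shape = "half_ellipse_mlo",
                       regions = regions)
  generate_phantom_mammogram(spec, seed)
}
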