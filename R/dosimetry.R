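#' Gamma-Knife-like plan specification
#'
#' A plan is a set of isotropic Gaussian "shots" (stand-ins for collimated
#' isocentres) plus the prescription rule: the prescription dose is delivered
#' at a stated fraction of the maximum dose (the 50% isodose by default, the
#' usual Gamma Knife convention, so the maximum is twice the prescription).
#'
#' @param shots data.frame with columns `x`, `y`, `z` (centre, mm),
#'   `sigma_mm` (> 0) and `weight` (> 0).
#' @param rx_dose prescription dose in Gy (default 12).
#' @param rx_isodose_fraction fraction of the maximum dose at which the
#'   prescription is delivered, in (0, 1) (default 0.5).
#' @return object of class `plan_spec`.
#' @export
plan_spec <- function(shots, rx_dose = 12, rx_isodose_fraction = 0.5) {
  shots <- as.data.frame(shots)
  need <- c("x", "y", "z", "sigma_mm", "weight")
  if (!all(need %in% names(shots)))
    stop("plan_spec: shots need columns ", paste(need, collapse = ", "))
  if (nrow(shots) < 1) stop("plan_spec: at least one shot required")
  if (any(shots$sigma_mm <= 0) || any(shots$weight <= 0))
    stop("plan_spec: sigma_mm and weight must be positive")
  if (!(rx_isodose_fraction > 0 && rx_isodose_fraction < 1))
    stop("plan_spec: rx_isodose_fraction must be in (0,1)")
  structure(list(shots = shots, rx_dose = rx_dose,
                 rx_isodose_fraction = rx_isodose_fraction),
            class = "plan_spec")
}

#' Simulate a Gaussian-shot dose grid
#'
#' Dose is the weighted sum of isotropic Gaussians, globally scaled so that
#' the maximum equals `rx_dose / rx_isodose_fraction` (24 Gy for a 12 Gy
#' prescription at the 50% isodose). Scaling makes the result invariant to a
#' common rescaling of the shot weights.
#'
#' @param plan a [plan_spec].
#' @param template [vol3d] defining the output lattice.
#' @return list of class `dose_grid` with element `dose` ([vol3d], Gy) and
#'   the plan.
#' @export
simulate_gk_dose <- function(plan, template) {
  stopifnot(inherits(plan, "plan_spec"), inherits(template, "vol3d"))
  d <- dim(template$data)
  crn <- voxel_to_mm(template, c(1, prod(d)))
  lo <- pmin(crn[1, ], crn[2, ]); hi <- pmax(crn[1, ], crn[2, ])
  sh <- plan$shots
  inb <- sh$x >= lo[1] & sh$x <= hi[1] & sh$y >= lo[2] & sh$y <= hi[2] &
    sh$z >= lo[3] & sh$z <= hi[3]
  if (any(!inb))
    stop("simulate_gk_dose: shot centre outside the grid (shot ",
         which(!inb)[1], ")")
  # per-axis physical coordinates via the affine (axis-aligned lattice)
  idx_mm <- function(ax) {
    v <- voxel_to_mm(template, 1 + (seq_len(d[ax]) - 1) *
                       c(1, d[1], d[1] * d[2])[ax])
    v[, ax]
  }
  X <- axis_array(idx_mm(1), d, 1)
  Y <- axis_array(idx_mm(2), d, 2)
  Z <- axis_array(idx_mm(3), d, 3)
  dose <- array(0, d)
  for (i in seq_len(nrow(sh))) {
    r2 <- (X - sh$x[i])^2 + (Y - sh$y[i])^2 + (Z - sh$z[i])^2
    dose <- dose + sh$weight[i] * exp(-r2 / (2 * sh$sigma_mm[i]^2))
  }
  dmax <- max(dose)
  if (dmax <= 0) stop("simulate_gk_dose: zero dose")
  dose <- dose * (plan$rx_dose / plan$rx_isodose_fraction / dmax)
  structure(list(dose = vol_like(dose, template), plan = plan),
            class = "dose_grid")
}

dose_data <- function(dose) {
  if (inherits(dose, "dose_grid")) dose$dose$data
  else as_data3(dose)
}

# Dose received by at least p percent of the voxels (empirical DVH, voxel
# counting, no interpolation).
dose_at_volume <- function(doses, p) {
  s <- sort(doses)
  s[max(1L, ceiling((1 - p / 100) * length(s)))]
}

#' DVH point metrics of a target
#'
#' @param dose a `dose_grid` or [vol3d] in Gy.
#' @param target non-empty [mask3d].
#' @return named numeric: `d_mean`, `d_max`, `d_min`, `d95` (Gy); `d95` is
#'   the dose received by at least 95% of the target volume.
#' @export
dvh_metrics <- function(dose, target) {
  dd <- dose_data(dose)
  m <- as_data3(target) > 0
  if (!any(m)) stop("dvh_metrics: empty target")
  v <- dd[m]
  c(d_mean = mean(v), d_max = max(v), d_min = min(v),
    d95 = dose_at_volume(v, 95))
}

#' Target coverage
#'
#' Fraction of the target receiving at least the prescription dose
#' (`TV_PIV / TV`).
#'
#' @inheritParams dvh_metrics
#' @param rx prescription dose, Gy.
#' @return scalar in `[0, 1]`.
#' @export
coverage_tc <- function(dose, target, rx) {
  dd <- dose_data(dose)
  m <- as_data3(target) > 0
  if (!any(m)) stop("coverage_tc: empty target")
  mean(dd[m] >= rx)
}

#' Paddick conformity index
#'
#' `PCI = TV_PIV^2 / (TV * PIV)` where TV is the target volume, PIV the
#' prescription isodose volume over the whole grid, and TV_PIV their
#' intersection. Penalizes both under-coverage and spill; 1 iff the
#' prescription isodose volume coincides with the target.
#'
#' @inheritParams coverage_tc
#' @return scalar in `[0, 1]`.
#' @export
paddick_ci <- function(dose, target, rx) {
  dd <- dose_data(dose)
  m <- as_data3(target) > 0
  if (!any(m)) stop("paddick_ci: empty target")
  piv <- dd >= rx
  npiv <- sum(piv)
  if (npiv == 0) stop("paddick_ci: empty prescription isodose volume")
  sum(m & piv)^2 / (sum(m) * npiv)
}

#' Paddick gradient index
#'
#' `GI = V(rx/2) / V(rx)`: volume of the half-prescription isodose over the
#' prescription isodose volume; lower is a steeper falloff. For a single
#' Gaussian shot prescribed at the 50% isodose the continuum value is
#' `2 * sqrt(2)`, independent of the shot width.
#'
#' @param dose a `dose_grid` or [vol3d] in Gy.
#' @param rx prescription dose, Gy.
#' @return scalar >= 1 whenever the maximum dose exceeds `rx`.
#' @export
gradient_index <- function(dose, rx) {
  dd <- dose_data(dose)
  n_rx <- sum(dd >= rx)
  if (n_rx == 0) stop("gradient_index: empty prescription isodose volume")
  sum(dd >= rx / 2) / n_rx
}

#' Homogeneity index
#'
#' Default definition: maximum target dose over the prescription dose
#' (`HI = Dmax/rx`; exactly 2 when the maximum lies in the target and the
#' plan is prescribed at the 50% isodose). The ICRU-style alternative
#' `(D2% - D98%) / D50%` is available via `mode = "icru"`.
#'
#' @inheritParams coverage_tc
#' @param mode `"dmax_over_rx"` (default) or `"icru"`.
#' @return unitless scalar.
#' @export
homogeneity_index <- function(dose, target, rx,
                              mode = c("dmax_over_rx", "icru")) {
  mode <- match.arg(mode)
  dd <- dose_data(dose)
  m <- as_data3(target) > 0
  if (!any(m)) stop("homogeneity_index: empty target")
  v <- dd[m]
  if (mode == "dmax_over_rx") {
    max(v) / rx
  } else {
    (dose_at_volume(v, 2) - dose_at_volume(v, 98)) / dose_at_volume(v, 50)
  }
}

# Exact two-sided Wilcoxon signed-rank p-value by the rank-sum distribution
# (dynamic programming over doubled midranks, so ties are handled exactly);
# normal approximation with tie and continuity corrections above n.
signed_rank_p <- function(d, exact_max_n = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Paired before/after comparison of plan metrics
#'
#' For each metric column the means and standard deviations before and after,
#' and a two-sided Wilcoxon signed-rank p-value for the paired differences
#' (exact via the rank-sum distribution for up to 25 informative pairs,
#' normal approximation above; zero differences are dropped).
#'
#' @param before,after data.frames with a `case` column and identical numeric
#'   metric columns; rows are paired by case id.
#' @param exact_max_n largest number of informative pairs for the exact test.
#' @param strict if `TRUE` (default) a metric with fewer than 5 informative
#'   (non-tied) pairs is an error; if `FALSE` its p-value is reported as `NA`
#'   (tied metrics are expected in practice, e.g. a hot-spot dose that both
#'   contours contain).
#' @return data.frame with one row per metric: `metric`, `mean_before`,
#'   `sd_before`, `mean_after`, `sd_after`, `n_informative`, `p_value`.
#' @export
compare_plans <- function(before, after, exact_max_n = 25, strict = TRUE) {
  before <- as.data.frame(before); after <- as.data.frame(after)
  if (!("case" %in% names(before)) || !("case" %in% names(after)))
    stop("compare_plans: both tables need a 'case' column")
  if (!setequal(before$case, after$case))
    stop("compare_plans: case ids differ between tables")
  after <- after[match(before$case, after$case), , drop = FALSE]
  metrics <- setdiff(intersect(names(before), names(after)), "case")
  if (!length(metrics)) stop("compare_plans: no shared metric columns")
  if (nrow(before) < 5) stop("compare_plans: need at least 5 pairs")
  rows <- lapply(metrics, function(mt) {
    x <- before[[mt]]; y <- after[[mt]]
    d <- y - x
    ninf <- sum(d != 0, na.rm = TRUE)
    if (ninf < 5 && strict)
      stop("compare_plans: fewer than 5 informative pairs for metric '",
           mt, "'")
    data.frame(metric = mt,
               mean_before = mean(x), sd_before = stats::sd(x),
               mean_after = mean(y), sd_after = stats::sd(y),
               n_informative = ninf,
               p_value = if (ninf >= 5) signed_rank_p(d, exact_max_n)
                         else NA_real_)
  })
  do.call(rbind, rows)
}
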