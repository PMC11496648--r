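## Reduction of each link's coefficient series to the three interaction
## properties: density-dependence of the interaction effect (IDD), temporal
## variability, and mean strength.

## Pair a link's coefficient records with the recipient's standardized
## density at the same (tank, year, census).
join_recipient_density <- function(series_df, recipient_cs) {
  keys <- composite_keys(recipient_cs)
  kk <- paste(keys$tank_id, keys$year, keys$census, sep = "\r")
  sk <- paste(series_df$tank_id, series_df$year, series_df$census, sep = "\r")
  idx <- match(sk, kk)
  if (anyNA(idx)) stop("coefficient record with no matching composite position")
  cbind(series_df, density = recipient_cs$values[idx])
}

#' Interaction density-dependence (IDD) regression for one link
#'
#' Ordinary least-squares regression of the link's S-map coefficients on
#' the recipient's standardized density at the same census, pooling all
#' treatments, tanks and years. The slope's sign is the IDD direction
#' (negative = potentially stabilizing, positive = potentially
#' destabilizing); its absolute value is the IDD magnitude. Statistical
#' significance is deliberately not used for the direction call.
#'
#' @param series_df Data frame of one link's coefficient records
#'   (`tank_id`, `year`, `census`, `coefficient`).
#' @param recipient_cs The recipient's `composite_series`.
#' @return List: `slope`, `intercept`, `r_squared`, `direction`
#'   (`"negative"`/`"positive"`; zero slope is reported as `"negative"`
#'   with `degenerate = TRUE`), `n`.
#' @export
idd_regression <- function(series_df, recipient_cs) {
  dat <- join_recipient_density(series_df, recipient_cs)
  if (nrow(dat) < 3L) stop("need at least 3 paired points for the IDD regression")
  if (stats::var(dat$density) == 0) stop("zero recipient density variance")
  fit <- stats::lm(coefficient ~ density, data = dat)
  sl <- unname(stats::coef(fit)["density"])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  ## slopes indistinguishable from zero at double precision: direction is
  ## "negative" by convention, flagged as degenerate
  degenerate <- abs(sl) < 1e-10 * max(1, abs(mean(dat$coefficient)))
  list(slope = if (degenerate) 0 else sl,
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       direction = if (!degenerate && sl > 0) "positive" else "negative",
       degenerate = degenerate, n = nrow(dat))
}

#' Classify a link's density-dependence against a permutation null
#'
#' Places the observed IDD slope against the null distribution of slopes
#' obtained by permuting the recipient densities over the paired records:
#' links whose slope magnitude stays inside the null band are classified
#' density-independent (variable interaction with no recipient-density
#' signal); the rest take the sign of the slope.
#'
#' @inheritParams idd_regression
#' @param n_perm Number of permutations (default 199).
#' @param alpha Two-sided band level (default 0.05).
#' @param seed Optional integer seed.
#' @return List: `class` (`"negative"`, `"positive"`,
#'   `"density_independent"`), `slope`, `p` (add-one permutation p for
#'   `|slope|`).
#' @export
classify_idd <- function(series_df, recipient_cs, n_perm = 199L,
                         alpha = 0.05, seed = NULL) {
  dat <- join_recipient_density(series_df, recipient_cs)
  if (stats::var(dat$density) == 0) stop("zero recipient density variance")
  slope_of <- function(x, y) stats::cov(x, y) / stats::var(x)
  obs <- slope_of(dat$density, dat$coefficient)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      abs(slope_of(sample(dat$density), dat$coefficient)), numeric(1))
  })
  p <- permutation_pvalue(abs(obs), null)
  cls <- if (p >= alpha) "density_independent" else
    if (obs > 0) "positive" else "negative"
  list(class = cls, slope = obs, p = p)
}

#' Mean strength and temporal variability of one link (controls only)
#'
#' Restricted to control-treatment records: per (year, tank) cell the mean
#' and standard deviation of the coefficients over the censuses are taken;
#' the averages of their absolute values over all cells give the link's
#' mean interaction strength and temporal variability. Cells with fewer
#' than two records have no SD and are dropped with a warning.
#'
#' @param series_df Data frame of one link's coefficient records.
#' @param control Treatment code of the controls (default `"C"`).
#' @return List: `mean_strength`, `temporal_variability`, `n_cells`.
#' @export
summarize_link <- function(series_df, control = "C") {
  ctl <- series_df[series_df$treatment == control, , drop = FALSE]
  if (nrow(ctl) == 0L) stop("no control records for this link")
  cell <- paste(ctl$year, ctl$tank_id, sep = "\r")
  ms <- tapply(ctl$coefficient, cell, mean)
  sds <- tapply(ctl$coefficient, cell, stats::sd)
  if (anyNA(sds)) {
    warning("dropping ", sum(is.na(sds)),
            " (year, replicate) cell(s) with < 2 coefficient records")
    ms <- ms[!is.na(sds)]
    sds <- sds[!is.na(sds)]
  }
  list(mean_strength = mean(abs(ms)),
       temporal_variability = mean(abs(sds)),
       n_cells = length(ms))
}

#' Link-property table for a set of interaction series
#'
#' @param is_obj An `interaction_series` (see [interaction_timeseries()]).
#' @param composites Named list of `composite_series` (for recipient
#'   densities).
#' @param control Control treatment code.
#' @return Data frame with one row per link: `donor`, `recipient`,
#'   `idd_slope`, `idd_direction`, `idd_magnitude`, `mean_strength`,
#'   `temporal_variability`.
#' @export
link_properties <- function(is_obj, composites, control = "C") {
  ser <- is_obj$series
  key <- paste(ser$donor, ser$recipient, sep = "->")
  out <- lapply(unique(key), function(k) {
    sub <- ser[key == k, , drop = FALSE]
    rc <- sub$recipient[1L]
    reg <- idd_regression(sub, composites[[rc]])
    sm <- summarize_link(sub, control = control)
    data.frame(donor = sub$donor[1L], recipient = rc,
               idd_slope = reg$slope, idd_direction = reg$direction,
               idd_magnitude = abs(reg$slope),
               mean_strength = sm$mean_strength,
               temporal_variability = sm$temporal_variability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Replicate-consistency two-way ANOVA for one link
#'
#' Fixed-effects two-way ANOVA of the link's S-map coefficients on
#' treatment, census date (categorical) and their interaction, with no
#' random effects and no autocorrelation structure; used to check that
#' temporal fluctuations of the interaction effect are consistent across
#' replicate tanks (variation should sit in census date and treatment, not
#' residuals).
#'
#' @param series_df Data frame of one link's coefficient records.
#' @return List: `table` (term, df, sum_sq, mean_sq, F, p) and
#'   `interaction_confounded` (TRUE when the full interaction has no
#'   replication, leaving no residual df).
#' @export
anova_consistency <- function(series_df) {
  dat <- data.frame(coefficient = series_df$coefficient,
                    treatment = factor(series_df$treatment),
                    census = factor(series_df$census))
  fit <- stats::aov(coefficient ~ treatment * census, data = dat)
  sm <- summary(fit)[[1L]]
  get_col <- function(nm) if (is.null(sm[[nm]])) rep(NA_real_, nrow(sm)) else sm[[nm]]
  tab <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                    sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
                    F = get_col("F value"), p = get_col("Pr(>F)"),
                    stringsAsFactors = FALSE)
  confounded <- !("Residuals" %in% tab$term) ||
    tab$df[tab$term == "Residuals"] == 0L
  if (confounded) {
    warning("interaction term confounded: no residual replication")
  }
  list(table = tab, interaction_confounded = confounded)
}
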