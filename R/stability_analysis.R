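## Population sensitivity to press disturbance and its regression on
## interaction properties.

#' Log response ratio of treatment vs control mean density
#'
#' `lrr = ln((T + 0.1) / (C + 0.1))` on raw (unstandardized) mean
#' densities; the +0.1 offsets keep zero means finite. The absolute value
#' of the LRR is the population sensitivity (an instability proxy).
#'
#' @param T_mean Mean raw density in the treatment.
#' @param C_mean Mean raw density in the controls.
#' @return The log response ratio.
#' @export
log_response_ratio <- function(T_mean, C_mean) {
  if (any(T_mean < 0) || any(C_mean < 0)) stop("densities must be non-negative")
  log((T_mean + 0.1) / (C_mean + 0.1))
}

#' Default recipient-function map
#'
#' Assigns each functional group a trophic role used as a covariate in the
#' sensitivity regression: producers (phytoplankton, macrophytes),
#' predators (the three predatory insect groups) and prey (the rest,
#' including molluscs and detritivores). Override by passing a named
#' character vector.
#'
#' @return Named character vector taxon -> one of `"producer"`,
#'   `"predator"`, `"prey"`.
#' @export
default_function_map <- function() {
  tx <- default_taxa()
  fn <- rep("prey", length(tx))
  names(fn) <- tx
  fn[c("phytoplankton", "macrophytes")] <- "producer"
  fn[c("phytophilous_pred", "benthic_pred", "neustonic_pred")] <- "predator"
  fn
}

#' Population sensitivity table for every taxon, year and contrast
#'
#' For each taxon and year, the treatment mean `T` and control mean `C`
#' are raw densities averaged over the arm's replicate tanks and all
#' censuses of that year; LRR and sensitivity `|LRR|` are computed for
#' each pesticide contrast.
#'
#' @param panel A `community_panel`.
#' @param contrasts Treatment codes contrasted against the control
#'   (default `c("I", "H", "IH")`).
#' @param control Control treatment code.
#' @return Data frame: `taxon`, `year`, `contrast`, `T_mean`, `C_mean`,
#'   `lrr`, `sensitivity` (complete design: 10 taxa x 3 years x 3
#'   contrasts = 90 rows). Missing treatment arms are omitted with a
#'   warning.
#' @export
sensitivity_table <- function(panel, contrasts = c("I", "H", "IH"),
                              control = "C") {
  stopifnot(inherits(panel, "community_panel"))
  taxa <- unique(panel$taxon)
  years <- sort(unique(panel$year))
  out <- list()
  for (tr in contrasts) {
    if (!any(panel$treatment == tr)) {
      warning("treatment arm '", tr, "' missing; contrast omitted")
      next
    }
    for (tx in taxa) {
      for (yr in years) {
        sub <- panel[panel$taxon == tx & panel$year == yr, , drop = FALSE]
        Tm <- mean(sub$raw_density[sub$treatment == tr])
        Cm <- mean(sub$raw_density[sub$treatment == control])
        lrr <- log_response_ratio(Tm, Cm)
        out[[length(out) + 1L]] <-
          data.frame(taxon = tx, year = yr, contrast = tr, T_mean = Tm,
                     C_mean = Cm, lrr = lrr, sensitivity = abs(lrr),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Assemble the link-by-year data for the sensitivity regression
#'
#' Each accepted link contributes one row per year carrying the link's
#' interaction properties (constant over years) and the recipient's
#' sensitivity in that year for the requested contrast. IDD magnitude is
#' ln-transformed; the response is `ln(1 + |LRR|)`.
#'
#' @param properties Link-property table (see [link_properties()]).
#' @param sensitivities Sensitivity table (see [sensitivity_table()]).
#' @param contrast Which pesticide contrast to model (`"I"`, `"H"` or
#'   `"IH"`).
#' @param function_map Named vector taxon -> recipient function (default
#'   [default_function_map()]).
#' @return Data frame ready for [sensitivity_regression()]. Links with
#'   zero IDD magnitude (ln undefined) are dropped with a warning.
#' @export
assemble_sensitivity_data <- function(properties, sensitivities, contrast,
                                      function_map = default_function_map()) {
  if (any(properties$idd_magnitude == 0)) {
    warning("dropping ", sum(properties$idd_magnitude == 0),
            " link(s) with zero IDD magnitude (ln undefined)")
    properties <- properties[properties$idd_magnitude > 0, , drop = FALSE]
  }
  sens <- sensitivities[sensitivities$contrast == contrast, , drop = FALSE]
  years <- sort(unique(sens$year))
  rows <- list()
  for (i in seq_len(nrow(properties))) {
    pr <- properties[i, ]
    for (yr in years) {
      s <- sens$sensitivity[sens$taxon == pr$recipient & sens$year == yr]
      if (length(s) != 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        link = paste(pr$donor, pr$recipient, sep = "->"),
        recipient = pr$recipient, year = yr,
        response = log1p(s),
        mean_strength = pr$mean_strength,
        temporal_variability = pr$temporal_variability,
        log_idd = log(pr$idd_magnitude),
        idd_direction = pr$idd_direction,
        recipient_function = unname(function_map[pr$recipient]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## Fixed-effect term layout of the sensitivity model. Sum-to-zero
## contrasts so that Type III (marginal) drops are meaningful.
sensitivity_model_matrix <- function(dat) {
  dat$idd_direction <- factor(dat$idd_direction,
                              levels = c("negative", "positive"))
  dat$recipient_function <- factor(dat$recipient_function)
  contr <- list(idd_direction = "contr.sum")
  terms <- list(mean_strength = "mean_strength",
                temporal_variability = "temporal_variability",
                idd = "log_idd",
                idd_direction = "idd_direction",
                `idd:direction` = "log_idd:idd_direction")
  form <- ~ mean_strength + temporal_variability + log_idd * idd_direction
  if (nlevels(dat$recipient_function) > 1L) {
    form <- stats::update(form, ~ . + recipient_function)
    terms$recipient_function <- "recipient_function"
    contr$recipient_function <- "contr.sum"
  }
  mm <- stats::model.matrix(form, dat, contrasts.arg = contr)
  assign <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  cols_by_term <- lapply(seq_along(labels), function(i) which(assign == i))
  names(cols_by_term) <- labels
  ## map display names onto model term labels
  col_map <- list(
    mean_strength = cols_by_term[["mean_strength"]],
    temporal_variability = cols_by_term[["temporal_variability"]],
    idd = cols_by_term[["log_idd"]],
    idd_direction = cols_by_term[["idd_direction"]],
    `idd:direction` = cols_by_term[["log_idd:idd_direction"]])
  if (!is.null(terms$recipient_function)) {
    col_map$recipient_function <- cols_by_term[["recipient_function"]]
  }
  list(mm = mm, col_map = col_map, data = dat)
}

fit_sensitivity_lmm <- function(dat, mm) {
  df <- data.frame(response = dat$response, link = dat$link,
                   year = factor(dat$year))
  df$X <- mm
  n_year <- nlevels(df$year)
  form <- if (n_year > 1L) response ~ 0 + X + (1 | link) + (1 | year)
          else response ~ 0 + X + (1 | link)
  suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
}

#' Mixed-model regression of population sensitivity on interaction
#' properties
#'
#' Fits a Gaussian linear mixed model by maximum likelihood with response
#' `ln(1 + |LRR|)` and fixed effects mean interaction strength, temporal
#' variability, ln IDD magnitude, IDD direction, their interaction, and
#' recipient function, with random intercepts for link identity and year.
#' Each term is tested by a Type III likelihood-ratio test: the term's
#' columns (under sum-to-zero contrasts) are dropped from the full model
#' and twice the log-likelihood difference is referred to chi-squared.
#'
#' @param dat Data frame from [assemble_sensitivity_data()] (or simulated
#'   with the same columns).
#' @return A `sensitivity_fit`: `table` (term, chi2, df, p), `model` (the
#'   full `lmer` fit), `coefficients` (fixed effects), `singular` flag.
#' @export
sensitivity_regression <- function(dat) {
  stopifnot(all(c("response", "link", "year", "mean_strength",
                  "temporal_variability", "log_idd", "idd_direction",
                  "recipient_function") %in% names(dat)))
  sm <- sensitivity_model_matrix(dat)
  full <- fit_sensitivity_lmm(sm$data, sm$mm)
  ll_full <- as.numeric(stats::logLik(full))
  tab <- list()
  for (term in names(sm$col_map)) {
    cols <- sm$col_map[[term]]
    red <- fit_sensitivity_lmm(sm$data, sm$mm[, -cols, drop = FALSE])
    chi2 <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red))))
    df <- length(cols)
    tab[[term]] <- data.frame(term = term, chi2 = chi2, df = df,
                              p = stats::pchisq(chi2, df, lower.tail = FALSE),
                              stringsAsFactors = FALSE)
  }
  coefs <- lme4::fixef(full)
  names(coefs) <- sub("^X", "", names(coefs))
  structure(list(table = do.call(rbind, c(tab, list(make.row.names = FALSE))),
                 model = full, coefficients = coefs,
                 singular = lme4::isSingular(full)),
            class = "sensitivity_fit")
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat("Type III likelihood-ratio tests (sensitivity ~ interaction properties)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-taxon pesticide-effect model with Dunnett contrasts
#'
#' Linear mixed model of a taxon's standardized density on treatment and
#' census week (categorical), with random intercepts for tank and year and
#' an AR-1 residual correlation within each tank-year series; fixed terms
#' are tested by Type III likelihood-ratio tests and each treatment is
#' compared to the control by two-sided Dunnett-adjusted contrasts
#' (multivariate-t adjustment via emmeans). If the AR-1 fit fails the
#' model is refit with independent residuals and flagged.
#'
#' @param panel A `community_panel`.
#' @param taxon Taxon to model.
#' @param composites Optional preprocessed composites (recomputed if
#'   omitted) supplying the standardized densities.
#' @param control Control treatment code.
#' @return List: `lr_table` (term, chi2, df, p), `contrasts` (Dunnett
#'   table vs control), `model`, `ar1` (TRUE if the AR-1 structure was
#'   retained), `adjustment` ("mvt").
#' @export
treatment_effect_model <- function(panel, taxon, composites = NULL,
                                   control = "C") {
  if (is.null(composites)) composites <- preprocess(panel)
  cs <- composites[[taxon]]
  if (is.null(cs)) stop("unknown taxon: ", taxon)
  keys <- composite_keys(cs)
  dat <- data.frame(value = cs$values,
                    treatment = stats::relevel(factor(keys$treatment),
                                               ref = control),
                    census = factor(keys$census),
                    tank = factor(keys$tank_id),
                    year = factor(keys$year))
  dat$unit <- interaction(dat$tank, dat$year, drop = TRUE)
  n_tank_per_arm <- tapply(dat$tank, dat$treatment,
                           function(x) length(unique(x)))
  if (any(n_tank_per_arm < 2L)) {
    warning("single tank in at least one arm: tank random intercept ",
            "unidentifiable from treatment")
  }
  fit_one <- function(form) {
    suppressWarnings(glmmTMB::glmmTMB(form, data = dat, REML = FALSE,
                                      dispformula = ~1))
  }
  form_ar1 <- stats::as.formula(
    "value ~ treatment + census + (1 | tank) + (1 | year) + ar1(0 + census | unit)")
  ar1_ok <- TRUE
  fit <- tryCatch(fit_one(form_ar1), error = function(e) NULL)
  if (is.null(fit) || !is.finite(as.numeric(stats::logLik(fit)))) {
    ar1_ok <- FALSE
    fit <- fit_one(value ~ treatment + census + (1 | tank) + (1 | year))
  }
  drop_fit <- function(drop_term) {
    f <- stats::as.formula(paste(". ~ . -", drop_term))
    form <- stats::update(stats::formula(fit), f)
    fit_one(form)
  }
  ll <- as.numeric(stats::logLik(fit))
  lr <- list()
  for (term in c("treatment", "census")) {
    red <- tryCatch(drop_fit(term), error = function(e) NULL)
    chi2 <- if (is.null(red)) NA_real_ else
      max(0, 2 * (ll - as.numeric(stats::logLik(red))))
    df <- nlevels(dat[[term]]) - 1L
    lr[[term]] <- data.frame(term = term, chi2 = chi2, df = df,
                             p = stats::pchisq(chi2, df, lower.tail = FALSE),
                             stringsAsFactors = FALSE)
  }
  emm <- emmeans::emmeans(fit, "treatment")
  ctr <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                           adjust = "mvt", side = "two-sided")
  list(lr_table = do.call(rbind, c(lr, list(make.row.names = FALSE))),
       contrasts = as.data.frame(ctr), model = fit, ar1 = ar1_ok,
       adjustment = "mvt")
}
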