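## Regularized multivariate S-map: locally weighted ridge regression over a
## mixed (recipient-lag + donor) embedding, with the recipient's per-capita
## growth as response. The fitted coefficient of a donor column at time t
## estimates the per-capita interaction effect
## d(1/N_r * dN_r/dt) / dN_d at that time.

#' S-map tuning grids
#'
#' Default grids scanned when tuning the local-weighting exponent theta
#' and the ridge penalty lambda.
#'
#' @return List with `theta` and `lambda` numeric vectors.
#' @export
smap_grids <- function() {
  list(theta = c(0, 0.1, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8),
       lambda = c(0, 0.0001, 0.001, 0.01, 0.1, 0.5, 1, 2))
}

#' Build a mixed (recipient + donor) embedding for one recipient
#'
#' Starts from the recipient's univariate lagged embedding at dimension E
#' and substitutes trailing lag coordinates by the donors' contemporaneous
#' standardized densities, keeping the total dimension at
#' `max(E, 1 + n_donors)` with at least one recipient lag column. With E =
#' 5 and three donors the coordinates are `{R_t, R_t-1, D1_t, D2_t, D3_t}`.
#' The response is the recipient's per-capita growth
#' `ln((N_{t+1}+1)/(N_t+1))` from raw densities; rows whose lags or
#' response leave the fragment are dropped.
#'
#' @param recipient A `composite_series`.
#' @param donors Named list of donor `composite_series` (the recipient's
#'   accepted CCM donors).
#' @param E The recipient's univariate embedding dimension.
#' @return A `mixed_embedding`: design matrix `X` (recipient-lag columns
#'   then one column per donor), response `y`, per-row composite index `t`
#'   and keys, `donor_cols` naming the donor columns.
#' @export
build_mixed_embedding <- function(recipient, donors, E) {
  stopifnot(inherits(recipient, "composite_series"))
  if (length(donors) == 0L) stop("no donors; link not S-mappable")
  stopifnot(!is.null(names(donors)), all(nzchar(names(donors))))
  n_d <- length(donors)
  dim_total <- max(E, 1L + n_d)
  n_lags <- dim_total - n_d          # recipient lag columns, always >= 1
  block <- build_lagged_block(recipient, n_lags, target = "growth")
  keep <- block$y_ok
  tvec <- block$t[keep]
  X <- block$X[keep, , drop = FALSE]
  colnames(X) <- sprintf("R_lag%d", seq_len(n_lags) - 1L)
  for (nm in names(donors)) {
    dv <- donors[[nm]]$values
    if (length(dv) != length(recipient$values)) {
      stop("donor '", nm, "' does not share the recipient's fragment structure")
    }
    X <- cbind(X, dv[tvec])
    colnames(X)[ncol(X)] <- nm
  }
  keys <- composite_keys(recipient)[tvec, , drop = FALSE]
  rownames(keys) <- NULL
  structure(list(X = X, y = block$y[keep], t = tvec, keys = keys,
                 E = E, n_lags = n_lags, donor_cols = names(donors),
                 recipient = recipient$taxon),
            class = "mixed_embedding")
}

#' @export
print.mixed_embedding <- function(x, ...) {
  cat(sprintf("<mixed_embedding '%s': %d rows, %d lag + %d donor columns>\n",
              x$recipient, nrow(x$X), x$n_lags, length(x$donor_cols)))
  invisible(x)
}

## Weighted-ridge solve at one target row. Returns c(intercept, slopes).
## The intercept is unpenalized; lambda applies to the weighted problem as
## given (no n rescaling). Solved by least squares on the sqrt-weighted
## design augmented with sqrt(lambda) rows, a route distinct from the
## explicit normal equations used as the testing oracle.
smap_solve <- function(X, y, w, lambda, row_label = "?") {
  d <- ncol(X)
  sw <- sqrt(w)
  A <- cbind(1, X) * sw
  b <- y * sw
  if (lambda > 0) {
    A <- rbind(A, cbind(0, diag(sqrt(lambda), d)))
    b <- c(b, rep(0, d))
  }
  fit <- tryCatch(qr.coef(qr(A), b), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    stop("singular weighted system at row ", row_label,
         " (consider lambda > 0)")
  }
  fit
}

#' Regularized S-map over a mixed embedding
#'
#' For every target row t*, rows are weighted by
#' `w_i = exp(-theta * d_i / dbar)` where `d_i` is the Euclidean distance
#' from row i to row t* in embedding space and `dbar` their mean, and the
#' local model `min sum_i w_i (y_i - b0 - b . x_i)^2 + lambda * ||b||^2`
#' (intercept unpenalized) is solved. With `exclude_self = TRUE` (the
#' default) the target row is left out of its own fit, so both the
#' reported coefficients and the RMSE are leave-one-out cross-validated.
#'
#' @param embed A `mixed_embedding`.
#' @param theta Local weighting exponent >= 0 (0 = global linear fit).
#' @param lambda Ridge penalty >= 0.
#' @param exclude_self Leave the target row out of its own fit.
#' @return List: `coefficients` (rows x (intercept + columns)),
#'   `predicted`, `rmse` and `skill` of the one-step predictions.
#' @export
regularized_smap <- function(embed, theta, lambda, exclude_self = TRUE) {
  stopifnot(inherits(embed, "mixed_embedding"), theta >= 0, lambda >= 0)
  X <- embed$X
  y <- embed$y
  n <- nrow(X)
  d <- ncol(X)
  if (n < d + 2L) stop("too few valid rows to fit the S-map")
  D <- as.matrix(stats::dist(X))
  coefs <- matrix(NA_real_, n, d + 1L,
                  dimnames = list(NULL, c("(Intercept)", colnames(X))))
  pred <- rep(NA_real_, n)
  for (p in seq_len(n)) {
    idx <- if (exclude_self) seq_len(n)[-p] else seq_len(n)
    dd <- D[p, idx]
    dbar <- mean(D[p, -p])
    if (dbar == 0) stop("degenerate embedding: all points coincide")
    w <- if (theta == 0) rep(1, length(idx)) else exp(-theta * dd / dbar)
    b <- smap_solve(X[idx, , drop = FALSE], y[idx], w, lambda,
                    row_label = p)
    coefs[p, ] <- b
    pred[p] <- b[1L] + sum(b[-1L] * X[p, ])
  }
  list(coefficients = coefs, predicted = pred,
       rmse = sqrt(mean((y - pred)^2)),
       skill = forecast_skill(y, pred))
}

#' Tune the S-map over the (theta, lambda) grids
#'
#' Evaluates the leave-one-out RMSE on the full grid and picks the
#' minimizer; ties go to the smaller lambda, then the smaller theta. For a
#' fixed theta the weighted cross-products are reused across lambdas.
#'
#' @param embed A `mixed_embedding`.
#' @param grids List with `theta` and `lambda` vectors (default
#'   [smap_grids()]).
#' @return List: `theta`, `lambda`, `rmse` (chosen) and the full `surface`
#'   data frame (theta, lambda, rmse).
#' @export
tune_smap <- function(embed, grids = smap_grids()) {
  X <- embed$X
  y <- embed$y
  n <- nrow(X)
  d <- ncol(X)
  if (n < d + 2L) stop("too few valid rows to tune the S-map")
  D <- as.matrix(stats::dist(X))
  thetas <- grids$theta
  lambdas <- grids$lambda
  Xi <- cbind(1, X)
  pen <- diag(c(0, rep(1, d)))
  sse <- matrix(0, length(thetas), length(lambdas))
  bad <- matrix(FALSE, length(thetas), length(lambdas))
  for (p in seq_len(n)) {
    idx <- seq_len(n)[-p]
    dd <- D[p, idx]
    dbar <- mean(dd)
    if (dbar == 0) stop("degenerate embedding: all points coincide")
    Xp <- Xi[idx, , drop = FALSE]
    yp <- y[idx]
    xrow <- Xi[p, ]
    for (ti in seq_along(thetas)) {
      w <- if (thetas[ti] == 0) rep(1, length(idx)) else
        exp(-thetas[ti] * dd / dbar)
      XtW <- t(Xp * w)
      A0 <- XtW %*% Xp
      c0 <- XtW %*% yp
      for (li in seq_along(lambdas)) {
        b <- tryCatch(solve(A0 + lambdas[li] * pen, c0),
                      error = function(e) NULL)
        if (is.null(b)) {
          bad[ti, li] <- TRUE
        } else {
          sse[ti, li] <- sse[ti, li] + (y[p] - sum(xrow * b))^2
        }
      }
    }
  }
  rmse <- sqrt(sse / n)
  rmse[bad] <- Inf
  surface <- data.frame(theta = rep(thetas, times = length(lambdas)),
                        lambda = rep(lambdas, each = length(thetas)),
                        rmse = as.vector(rmse))
  best <- min(surface$rmse)
  cand <- surface[surface$rmse == best, , drop = FALSE]
  cand <- cand[order(cand$lambda, cand$theta), , drop = FALSE]
  list(theta = cand$theta[1L], lambda = cand$lambda[1L],
       rmse = cand$rmse[1L], surface = surface)
}

#' Time-varying interaction effects for every accepted link
#'
#' One regularized S-map model is fitted per recipient (tuned on the
#' recipient's composite across all treatments and years); the coefficient
#' series of each donor column is the per-capita interaction effect of
#' that donor->recipient link, mapped back to (tank, treatment, year,
#' census) keys.
#'
#' @param links Data frame with columns `donor`, `recipient` (accepted CCM
#'   links).
#' @param composites Named list of `composite_series`.
#' @param E Named integer vector of embedding dimensions per taxon.
#' @param grids Tuning grids (default [smap_grids()]).
#' @param theta,lambda Optional fixed values bypassing tuning.
#' @return An `interaction_series`: `series` (long data frame: donor,
#'   recipient, tank_id, treatment, year, census, coefficient) and
#'   `models` (per recipient: chosen theta, lambda, rmse, rho).
#' @export
interaction_timeseries <- function(links, composites, E,
                                   grids = smap_grids(), theta = NULL,
                                   lambda = NULL) {
  stopifnot(all(c("donor", "recipient") %in% names(links)))
  recips <- unique(links$recipient)
  ser <- list()
  models <- list()
  for (rc in recips) {
    dns <- links$donor[links$recipient == rc]
    emb <- build_mixed_embedding(composites[[rc]],
                                 composites[dns], E[[rc]])
    if (is.null(theta) || is.null(lambda)) {
      tn <- tune_smap(emb, grids = grids)
      th <- tn$theta; la <- tn$lambda
    } else {
      th <- theta; la <- lambda
    }
    fit <- regularized_smap(emb, th, la)
    models[[rc]] <- data.frame(recipient = rc, theta = th, lambda = la,
                               rmse = fit$rmse, rho = fit$skill$rho,
                               stringsAsFactors = FALSE)
    for (dn in dns) {
      ser[[paste(dn, rc, sep = "->")]] <-
        data.frame(donor = dn, recipient = rc, emb$keys[c("tank_id",
                   "treatment", "year", "census")],
                   coefficient = fit$coefficients[, dn],
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(series = do.call(rbind, c(ser, list(make.row.names = FALSE))),
                 models = do.call(rbind, c(models, list(make.row.names = FALSE)))),
            class = "interaction_series")
}

#' @export
print.interaction_series <- function(x, ...) {
  nl <- nrow(unique(x$series[, c("donor", "recipient")]))
  cat(sprintf("<interaction_series: %d links, %d coefficient records>\n",
              nl, nrow(x$series)))
  invisible(x)
}

#' Write interaction coefficient series and per-recipient S-map parameters
#'
#' @param is_obj An `interaction_series`.
#' @param csv_path Output CSV of the coefficient series.
#' @param models_path Optional JSON of chosen (theta, lambda, rmse) per
#'   recipient.
#' @return Invisibly `csv_path`.
#' @export
write_interactions <- function(is_obj, csv_path, models_path = NULL) {
  utils::write.csv(is_obj$series, csv_path, row.names = FALSE)
  if (!is.null(models_path)) {
    jsonlite::write_json(is_obj$models, models_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}
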