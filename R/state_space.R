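## State-space reconstruction over fragmented composites.
##
## All embeddings respect fragment boundaries: a delay vector is valid only
## if every lag (and, when a one-step-ahead target is attached, the t+1
## target) lies inside the same tank-year fragment.

#' Build a time-delay (lagged) block from a composite series
#'
#' Rows are delay vectors `(x_t, x_{t-1}, ..., x_{t-E+1})` (tau = 1) for
#' every composite position t whose lags all fall inside the same
#' fragment. An optional prediction target is attached:
#' \describe{
#'   \item{`"tp1"`}{the series' own next value `x_{t+1}` (simplex
#'     projection); invalid at fragment ends.}
#'   \item{`"growth"`}{the recipient's per-capita growth
#'     `ln((N_{t+1}+1)/(N_t+1))` from raw densities (S-map response);
#'     invalid at fragment ends.}
#'   \item{`"none"`}{no target (cross mapping attaches its own).}
#' }
#'
#' @param series A `composite_series`.
#' @param E Embedding dimension (number of lagged coordinates), >= 1.
#' @param target One of `"tp1"`, `"growth"`, `"none"`.
#' @return A `lagged_block`: matrix `X` (rows x E), composite index `t`,
#'   `fragment` per row, target `y` with validity mask `y_ok`.
#' @export
build_lagged_block <- function(series, E, target = c("tp1", "growth", "none")) {
  stopifnot(inherits(series, "composite_series"), E >= 1)
  target <- match.arg(target)
  f <- series$fragments
  if (E >= min(f$len)) {
    stop(sprintf("fragment too short to embed: E=%d with shortest fragment length %d",
                 E, min(f$len)))
  }
  v <- series$values
  rows_t <- integer(0)
  for (i in seq_len(nrow(f))) {
    tt <- seq.int(f$start[i] + E - 1L, f$start[i] + f$len[i] - 1L)
    rows_t <- c(rows_t, tt)
  }
  X <- vapply(seq_len(E) - 1L, function(l) v[rows_t - l], numeric(length(rows_t)))
  X <- matrix(X, nrow = length(rows_t), ncol = E)
  colnames(X) <- sprintf("lag%d", seq_len(E) - 1L)
  frag <- series$fragment[rows_t]

  y <- rep(NA_real_, length(rows_t))
  y_ok <- rep(TRUE, length(rows_t))
  if (target == "tp1") {
    nxt <- rows_t + 1L
    y_ok <- nxt <= length(v) & series$fragment[pmin(nxt, length(v))] == frag
    y[y_ok] <- v[nxt[y_ok]]
  } else if (target == "growth") {
    g <- growth_series(series)
    y <- g[rows_t]
    y_ok <- !is.na(y)
  }
  structure(list(E = E, X = X, t = rows_t, fragment = frag, y = y, y_ok = y_ok,
                 taxon = series$taxon),
            class = "lagged_block")
}

#' @export
print.lagged_block <- function(x, ...) {
  cat(sprintf("<lagged_block E=%d: %d rows (%d with valid target)>\n",
              x$E, nrow(x$X), sum(x$y_ok)))
  invisible(x)
}

## Simplex neighbor weights for a distance vector d over candidate rows.
## k nearest are used; ties broken by candidate order (fragment, position).
## Exact-duplicate (zero-distance) neighbors take all the weight when
## present; otherwise weights are exp(-d/d1) with d1 the nearest distance.
simplex_weights <- function(d, k) {
  ord <- order(d)                       # stable: ties keep candidate order
  nb <- ord[seq_len(min(k, length(d)))]
  dk <- d[nb]
  if (dk[1L] == 0) {
    w <- as.numeric(dk == 0)
  } else {
    w <- exp(-dk / dk[1L])
  }
  list(nb = nb, w = w)
}

#' Simplex projection forecast over a lagged block
#'
#' k = E+1 nearest-neighbor forecasting in delay space: the forecast for a
#' row is the weight-averaged target of its k nearest library rows
#' (Euclidean distance), with weights `exp(-d_i/d_1)`. Under leave-one-out
#' cross-validation the predictee row and any row at zero distance from it
#' (exact duplicate coordinates) are excluded from its own neighbor set.
#'
#' @param block A `lagged_block` with a valid target (`tp1` or `growth`).
#' @param loocv Exclude the predictee (and its exact duplicates) from its
#'   neighbor set.
#' @return List with `predictions` (data frame: composite index `t`,
#'   `observed`, `predicted`) and `skill` (`rho`, `mae`, `rmse`,
#'   `n_predictions`).
#' @export
simplex_forecast <- function(block, loocv = TRUE) {
  stopifnot(inherits(block, "lagged_block"))
  lib <- which(block$y_ok)
  k <- block$E + 1L
  if (length(lib) < k + 1L) {
    stop(sprintf("fewer rows (%d) than needed for %d neighbors plus predictee",
                 length(lib), k))
  }
  D <- as.matrix(stats::dist(block$X[lib, , drop = FALSE]))
  y <- block$y[lib]
  pred <- rep(NA_real_, length(lib))
  for (i in seq_along(lib)) {
    d <- D[i, ]
    cand <- seq_along(lib)
    if (loocv) cand <- cand[cand != i & d[cand] > 0]
    if (length(cand) < k) stop("fewer neighbors than E+1 available")
    sw <- simplex_weights(d[cand], k)
    nb <- cand[sw$nb]
    pred[i] <- sum(sw$w * y[nb]) / sum(sw$w)
  }
  skill <- forecast_skill(y, pred)
  list(predictions = data.frame(t = block$t[lib], observed = y,
                                predicted = pred),
       skill = skill)
}

forecast_skill <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  rho <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_ else
    stats::cor(obs, pred)
  list(rho = rho,
       mae = mean(abs(obs - pred)),
       rmse = sqrt(mean((obs - pred)^2)),
       n_predictions = length(obs))
}

#' Choose the embedding dimension by cross-validated simplex skill
#'
#' Scans E over `Emin:Emax`, scoring one-step-ahead simplex projection
#' under leave-one-out cross-validation by Pearson rho, MAE and RMSE. The
#' returned choice minimizes RMSE by default (override with `criterion`);
#' the full skill table is always returned, and a flag is raised when the
#' three criteria disagree on the best E.
#'
#' @param series A `composite_series`.
#' @param Emin,Emax Scan range (defaults 2 and 6).
#' @param criterion `"rmse"` (default), `"mae"` or `"rho"`.
#' @return List: `E` (chosen), `table` (E, rho, mae, rmse, n), `agreement`
#'   (logical: all three criteria pick the same E).
#' @export
select_embedding_dimension <- function(series, Emin = 2L, Emax = 6L,
                                       criterion = c("rmse", "mae", "rho")) {
  criterion <- match.arg(criterion)
  Es <- seq.int(Emin, Emax)
  tab <- data.frame(E = Es, rho = NA_real_, mae = NA_real_, rmse = NA_real_,
                    n = NA_integer_)
  for (i in seq_along(Es)) {
    block <- build_lagged_block(series, Es[i], target = "tp1")
    sk <- simplex_forecast(block, loocv = TRUE)$skill
    tab$rho[i] <- sk$rho
    tab$mae[i] <- sk$mae
    tab$rmse[i] <- sk$rmse
    tab$n[i] <- sk$n_predictions
  }
  pick <- c(rho = tab$E[which.max(tab$rho)],
            mae = tab$E[which.min(tab$mae)],
            rmse = tab$E[which.min(tab$rmse)])
  agreement <- length(unique(pick)) == 1L
  chosen <- unname(pick[[criterion]])
  list(E = chosen, table = tab, agreement = agreement, criterion = criterion)
}

#' Choose embedding dimensions for every taxon
#'
#' @param composites Named list of `composite_series`.
#' @inheritParams select_embedding_dimension
#' @return Named integer vector of chosen E per taxon, with the full skill
#'   tables in attribute `"tables"`.
#' @export
select_embeddings <- function(composites, Emin = 2L, Emax = 6L,
                              criterion = "rmse") {
  res <- lapply(composites, select_embedding_dimension, Emin = Emin,
                Emax = Emax, criterion = criterion)
  out <- vapply(res, `[[`, integer(1), "E")
  attr(out, "tables") <- lapply(res, `[[`, "table")
  out
}
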