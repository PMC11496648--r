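#' @keywords internal
"_PACKAGE"

#' Default functional-group labels
#'
#' The ten functional groups used as network nodes: two producers
#' (phytoplankton, macrophytes), five consumer/prey groups and three
#' predatory insect groups plus molluscs. Macrophyte "density" is a
#' coverage proportion in `[0, 1]`; all other groups are counts per sample.
#'
#' @return Character vector of length 10.
#' @export
default_taxa <- function() {
  c("phytoplankton", "rotifers", "crust_zoopl", "macrophytes",
    "detritivores", "herbivores", "phytophilous_pred", "benthic_pred",
    "neustonic_pred", "molluscs")
}

#' Treatment codes
#'
#' `C` control, `I` insecticide, `H` herbicide, `IH` both pesticides.
#' @return Character vector of length 4.
#' @export
treatment_levels <- function() c("C", "I", "H", "IH")

panel_columns <- c("tank_id", "treatment", "year", "census", "taxon", "raw_density")

#' Construct and validate a community panel
#'
#' A community panel is a long-format table of raw densities keyed by
#' (tank, treatment, year, census, taxon). Validation enforces the design
#' constraints required downstream: unique keys, non-negative densities,
#' and censuses forming a gap-free run within every (tank, year, taxon)
#' fragment (the sampling interval must be constant for delay embedding).
#'
#' @param df Data frame with columns `tank_id`, `treatment`, `year`,
#'   `census`, `taxon`, `raw_density`.
#' @return The validated panel, sorted by (treatment, tank, year, census,
#'   taxon), with class `community_panel`.
#' @export
community_panel <- function(df) {
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[panel_columns]
  df$tank_id <- as.character(df$tank_id)
  df$treatment <- as.character(df$treatment)
  df$taxon <- as.character(df$taxon)
  df$year <- as.integer(df$year)
  df$census <- as.integer(df$census)
  df$raw_density <- as.numeric(df$raw_density)

  bad_trt <- setdiff(unique(df$treatment), treatment_levels())
  if (length(bad_trt) > 0L) {
    stop("unknown treatment code(s): ", paste(bad_trt, collapse = ", "))
  }
  if (anyNA(df$raw_density)) stop("raw_density contains missing values")
  if (any(df$raw_density < 0)) {
    i <- which(df$raw_density < 0)[1L]
    stop(sprintf("negative density at (tank=%s, year=%d, census=%d, taxon=%s)",
                 df$tank_id[i], df$year[i], df$census[i], df$taxon[i]))
  }

  key <- paste(df$tank_id, df$year, df$census, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicated key (tank=%s, year=%d, census=%d, taxon=%s)",
                 df$tank_id[i], df$year[i], df$census[i], df$taxon[i]))
  }

  ## censuses inside a fragment must be consecutive (constant interval)
  frag <- split(df$census, paste(df$tank_id, df$year, df$taxon, sep = "\r"))
  for (nm in names(frag)) {
    cs <- sort(frag[[nm]])
    if (length(cs) > 10L) {
      stop("more than 10 censuses in fragment ", gsub("\r", "/", nm))
    }
    if (length(cs) > 1L && any(diff(cs) != 1L)) {
      stop("missing census inside fragment ", gsub("\r", "/", nm),
           ": censuses must form a consecutive run")
    }
  }

  ## one tank must sit in exactly one treatment
  tt <- unique(df[, c("tank_id", "treatment")])
  if (anyDuplicated(tt$tank_id)) {
    stop("tank assigned to more than one treatment: ",
         tt$tank_id[duplicated(tt$tank_id)][1L])
  }

  ord <- order(df$treatment, df$tank_id, df$year, df$census, df$taxon)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("community_panel", "data.frame")
  df
}

#' Read a community panel from CSV
#'
#' @param path Path to a UTF-8 CSV file whose header names the six panel
#'   fields (`tank_id,treatment,year,census,taxon,raw_density`).
#' @return A validated `community_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  community_panel(df)
}

#' Check the full experimental design of a panel
#'
#' Asserts the replicated mesocosm layout: exactly two tanks per
#' treatment, all four treatments present.
#'
#' @param panel A `community_panel`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_design <- function(panel) {
  tt <- unique(panel[, c("tank_id", "treatment")])
  n_per <- table(factor(tt$treatment, levels = treatment_levels()))
  if (any(n_per != 2L)) {
    stop("design requires exactly 2 tanks per treatment; got ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Composite series

#' Assemble a composite series from fragment value vectors
#'
#' Low-level constructor used by [preprocess()] and by analyses of
#' non-panel data (e.g. simulated coupled maps split into fragments).
#' Fragments are concatenated in the order given; standardization (and the
#' optional ln(x+1) transform) is performed on the composite as a whole,
#' never per fragment.
#'
#' @param fragments List of numeric vectors of raw values (each a fragment,
#'   length >= 2).
#' @param taxon Label for the series.
#' @param ln Apply ln(x+1) before standardizing?
#' @param keys Optional data frame with one row per fragment and columns
#'   `tank_id`, `treatment`, `year`. Defaults to synthetic identifiers.
#' @param first_census Integer vector (recycled) giving the census index of
#'   each fragment's first point; census indices are `first_census`,
#'   `first_census + 1`, ...
#' @return A `composite_series`: standardized `values`, pre-standardization
#'   `logp`, untransformed `raw`, a `fragments` offset table (half-open
#'   `[start, start + len)` tiling), per-position `census`/`fragment`
#'   indices and `meta` (transform flag, composite mean and sd).
#' @export
as_composite <- function(fragments, taxon = "x", ln = FALSE, keys = NULL,
                         first_census = 1L) {
  stopifnot(is.list(fragments), length(fragments) > 0L)
  lens <- lengths(fragments)
  if (any(lens < 2L)) stop("fragments must have length >= 2")
  n_frag <- length(fragments)
  if (is.null(keys)) {
    keys <- data.frame(tank_id = sprintf("t%02d", seq_len(n_frag)),
                       treatment = "C", year = 1L,
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(keys) == n_frag)
  first_census <- rep_len(as.integer(first_census), n_frag)

  raw <- unlist(fragments, use.names = FALSE)
  if (ln) {
    if (any(raw < 0)) stop("negative values under ln(x+1) transform")
    logp <- log(raw + 1)
  } else {
    logp <- raw
  }
  m <- mean(logp)
  s <- stats::sd(logp)
  if (!is.finite(s) || s == 0) {
    stop("constant series, not embeddable (zero composite variance) for taxon ",
         taxon)
  }
  values <- (logp - m) / s

  starts <- cumsum(c(1L, lens[-n_frag]))
  frag_tab <- data.frame(fragment_id = seq_len(n_frag),
                         tank_id = keys$tank_id,
                         treatment = keys$treatment,
                         year = keys$year,
                         start = starts, len = as.integer(lens),
                         stringsAsFactors = FALSE)
  census <- unlist(mapply(function(fc, l) seq.int(fc, length.out = l),
                          first_census, lens, SIMPLIFY = FALSE))
  fragment <- rep.int(seq_len(n_frag), lens)

  structure(list(taxon = taxon, values = values, logp = logp, raw = raw,
                 fragments = frag_tab, census = as.integer(census),
                 fragment = fragment,
                 meta = list(ln = ln, mean = m, sd = s)),
            class = "composite_series")
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf("<composite_series '%s': %d points, %d fragments, ln=%s>\n",
              x$taxon, length(x$values), nrow(x$fragments), x$meta$ln))
  invisible(x)
}

#' Preprocess a panel into standardized composite series
#'
#' Per taxon, fragments (one per tank-year) are concatenated in
#' (treatment, tank, year) order, transformed by ln(x+1) (identity for
#' taxa in `ln_exempt`, by default the macrophyte coverage proportions),
#' and z-standardized to zero mean and unit variance across the whole
#' composite. Raw densities are carried alongside the standardized values
#' because per-capita growth is always computed from raw densities.
#'
#' @param panel A `community_panel`.
#' @param ln_exempt Character vector of taxa standardized without the
#'   ln(x+1) transform.
#' @return Named list of `composite_series`, one per taxon.
#' @export
preprocess <- function(panel, ln_exempt = "macrophytes") {
  stopifnot(inherits(panel, "community_panel"))
  taxa <- sort(unique(panel$taxon))
  out <- vector("list", length(taxa))
  names(out) <- taxa
  for (tx in taxa) {
    sub <- panel[panel$taxon == tx, , drop = FALSE]
    fid <- paste(sub$treatment, sub$tank_id, sub$year, sep = "\r")
    ufid <- unique(fid)  # panel is sorted, so this preserves design order
    frags <- vector("list", length(ufid))
    keys <- data.frame(tank_id = character(0), treatment = character(0),
                       year = integer(0), stringsAsFactors = FALSE)
    fc <- integer(length(ufid))
    for (i in seq_along(ufid)) {
      rows <- sub[fid == ufid[i], , drop = FALSE]
      rows <- rows[order(rows$census), , drop = FALSE]
      frags[[i]] <- rows$raw_density
      keys <- rbind(keys, data.frame(tank_id = rows$tank_id[1L],
                                     treatment = rows$treatment[1L],
                                     year = rows$year[1L],
                                     stringsAsFactors = FALSE))
      fc[i] <- rows$census[1L]
    }
    out[[tx]] <- as_composite(frags, taxon = tx, ln = !(tx %in% ln_exempt),
                              keys = keys, first_census = fc)
  }
  out
}

#' Invert the composite transform
#'
#' Recovers the raw densities from the standardized values using the
#' stored transform metadata.
#'
#' @param cs A `composite_series`.
#' @return Numeric vector of raw values.
#' @export
invert_composite <- function(cs) {
  stopifnot(inherits(cs, "composite_series"))
  logp <- cs$values * cs$meta$sd + cs$meta$mean
  if (cs$meta$ln) exp(logp) - 1 else logp
}

#' Per-position fragment keys of a composite
#'
#' @param cs A `composite_series`.
#' @return Data frame with one row per composite position: `tank_id`,
#'   `treatment`, `year`, `census`, `fragment`, `position`.
#' @export
composite_keys <- function(cs) {
  f <- cs$fragments
  idx <- cs$fragment
  data.frame(tank_id = f$tank_id[idx], treatment = f$treatment[idx],
             year = f$year[idx], census = cs$census,
             fragment = idx,
             position = seq_along(cs$values) - f$start[idx] + 1L,
             stringsAsFactors = FALSE)
}

#' Per-capita growth rate of a raw density fragment
#'
#' Computes `g_t = ln((N_{t+1} + 1) / (N_t + 1))` along a single fragment;
#' the +1 offset keeps zero densities finite. Growth is never computed
#' across fragment boundaries: apply this per fragment, or use
#' [growth_series()] for a boundary-aware composite version.
#'
#' @param N Numeric vector of raw (untransformed) densities, length >= 2.
#' @return Numeric vector of length `length(N) - 1`.
#' @export
per_capita_growth <- function(N) {
  if (length(N) < 2L) stop("fragment of length < 2: cannot compute growth")
  if (any(N < 0)) stop("negative density")
  diff(log(N + 1))
}

#' Per-capita growth aligned to a composite series
#'
#' @param cs A `composite_series`.
#' @return Numeric vector of the composite's length: growth at time t
#'   (towards t+1) from raw densities, `NA` at the last point of each
#'   fragment where no within-fragment successor exists.
#' @export
growth_series <- function(cs) {
  g <- rep(NA_real_, length(cs$values))
  f <- cs$fragments
  for (i in seq_len(nrow(f))) {
    idx <- seq.int(f$start[i], length.out = f$len[i])
    g[idx[-length(idx)]] <- per_capita_growth(cs$raw[idx])
  }
  g
}

#' Write composite series and transform metadata to disk
#'
#' @param composites Named list of `composite_series`.
#' @param csv_path Output CSV (`taxon,fragment_id,position,census,value`).
#' @param meta_path Optional JSON path for transform metadata and fragment
#'   offsets.
#' @return Invisibly the CSV path.
#' @export
write_composites <- function(composites, csv_path, meta_path = NULL) {
  rows <- lapply(composites, function(cs) {
    k <- composite_keys(cs)
    data.frame(taxon = cs$taxon, fragment_id = k$fragment,
               position = k$position, census = k$census, value = cs$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- lapply(composites, function(cs) {
      list(taxon = cs$taxon, ln = cs$meta$ln, mean = cs$meta$mean,
           sd = cs$meta$sd, fragments = cs$fragments)
    })
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
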