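#' Read per-cell lifespans from a delimited file
#'
#' Expects long format with a header and two columns, `strain_id` and
#' `lifespan` (one row per cell), comma- or tab-delimited (sniffed from
#' the header unless `delim` is given). Lifespans must be numeric and
#' strictly positive; offending rows are reported by line number.
#'
#' @param path path to the file.
#' @param delim `","` or `"\t"`; `NULL` (default) sniffs from the header.
#' @param format `"long"` (default) or `"wide"`. In wide format each
#'   column is one strain (header = strain label) and each row one cell;
#'   ragged strains are padded with empty cells.
#' @return A named list of [lifespan_dataset()] objects, one per strain,
#'   in order of first appearance.
#' @export
read_lifespans <- function(path, delim = NULL, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim))
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (format == "wide") {
    out <- lapply(names(tab), function(s) {
      raw <- tab[[s]][tab[[s]] != ""]
      num <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(num) | !is.finite(num) | num <= 0)
      if (length(bad) > 0)
        stop(sprintf("invalid lifespan for strain '%s' in %s: '%s'",
                     s, path, raw[bad[1]]))
      lifespan_dataset(s, num)
    })
    names(out) <- names(tab)
    return(out)
  }
  if (!all(c("strain_id", "lifespan") %in% names(tab)))
    stop("lifespan file must have header columns `strain_id` and `lifespan`")
  ls_num <- suppressWarnings(as.numeric(tab$lifespan))
  bad <- which(is.na(ls_num) | !is.finite(ls_num) | ls_num <= 0)
  if (length(bad) > 0)
    stop(sprintf("invalid lifespan at line %d of %s: '%s' (must be a positive number)",
                 bad[1] + 1L, path, tab$lifespan[bad[1]]))
  strains <- unique(tab$strain_id)
  out <- lapply(strains, function(s)
    lifespan_dataset(s, ls_num[tab$strain_id == s]))
  names(out) <- strains
  out
}

#' Write lifespan datasets to a long-format CSV
#'
#' Writes the dialect [read_lifespans()] reads: header
#' `strain_id,lifespan`, one row per cell. The round trip is lossless at
#' full double precision.
#'
#' @param datasets a [lifespan_dataset()] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lifespans <- function(datasets, path) {
  if (inherits(datasets, "lifespan_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "lifespan_dataset")))
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(strain_id = d$strain,
               lifespan = format(d$lifespans, digits = 17, trim = TRUE,
                                 scientific = FALSE),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit all models per strain with bootstrap, as a parameter table
#'
#' Runs [bootstrap_fit()] for the network, Gompertz and Weibull models on
#' each dataset and assembles the per-strain rows of a strain parameter
#' table: bootstrap mean and sd per parameter and per-model AIC, plus the
#' strain's average lifespan. Each strain's bootstrap is seeded
#' deterministically from `seed`.
#'
#' @param datasets a list of [lifespan_dataset()] objects (as returned by
#'   [read_lifespans()]).
#' @param B bootstrap resamples per model (default 100).
#' @param seed integer master seed.
#' @param ... passed to [bootstrap_fit()].
#' @return A data frame with the column layout of [wild_isolates()] plus
#'   `B` and `seed`.
#' @export
strain_fit_table <- function(datasets, B = 100, seed = 1, ...) {
  if (inherits(datasets, "lifespan_dataset")) datasets <- list(datasets)
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    boots <- lapply(c("network", "gompertz", "weibull"), function(mod)
      bootstrap_fit(mod, d, B = B, seed = sub_seed, ...))
    names(boots) <- c("network", "gompertz", "weibull")
    nb <- boots$network; gb <- boots$gompertz; wb <- boots$weibull
    data.frame(
      strain = d$strain,
      avg_rls = mean(d$lifespans),
      avg_rls_sd = stats::sd(d$lifespans) / sqrt(length(d$lifespans)),
      net_R = nb$mean[["R"]], net_R_sd = nb$sd[["R"]],
      t0 = nb$mean[["t0"]], t0_sd = nb$sd[["t0"]],
      n = nb$mean[["n"]], n_sd = nb$sd[["n"]],
      gomp_R = gb$mean[["R"]], gomp_R_sd = gb$sd[["R"]],
      gomp_G = gb$mean[["G"]], gomp_G_sd = gb$sd[["G"]],
      aic_weibull = wb$aic_mean, aic_weibull_sd = wb$aic_sd,
      aic_gompertz = gb$aic_mean, aic_gompertz_sd = gb$aic_sd,
      aic_network = nb$aic_mean, aic_network_sd = nb$aic_sd,
      B = B, seed = seed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fitted strain parameter table as TSV
#'
#' Parameters are rounded to 4 decimals and AICs to 2; column order is
#' fixed, so repeated runs produce byte-identical files. The written file
#' is readable by [read_strain_table()].
#'
#' @param results a data frame from [strain_fit_table()] (or any data
#'   frame with its columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  out <- results
  par_cols <- intersect(names(out),
                        c("avg_rls", "avg_rls_sd", "net_R", "net_R_sd",
                          "t0", "t0_sd", "n", "n_sd",
                          "gomp_R", "gomp_R_sd", "gomp_G", "gomp_G_sd"))
  aic_cols <- grep("^aic_", names(out), value = TRUE)
  out[par_cols] <- lapply(out[par_cols], round, digits = 4)
  out[aic_cols] <- lapply(out[aic_cols], round, digits = 2)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
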