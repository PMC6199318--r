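# Plain-text I/O: traces as TSV, velocity datasets as CSV, densities as TSV.
# All writers embed provenance (seed, config hash) as '#key=value' comment
# lines so that outputs are self-describing and diff-able.

write_meta_lines <- function(con, meta) {
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (inherits(v, "rate_constants")) {
      v <- sprintf("%g,%g,%g,%g", v$kB_off, v$kB_b, v$kA_off, v$kA_b)
    }
    if (is.null(v) || length(v) == 0L) next
    writeLines(sprintf("#%s=%s", nm, paste(format(v, digits = 15),
                                           collapse = ",")), con)
  }
}

read_meta_lines <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      meta[[key]] <- if (any(is.na(num))) val else num
    }
  }
  meta
}

#' Write / read a FRET trace
#'
#' Traces are tab-separated with a `time_s` column plus either a `fret`
#' column, or `donor` and `acceptor` intensity columns (in which case the
#' efficiency is computed on load via [compute_fret()]). Ground-truth
#' `state` / `position` columns are present only for synthetic traces.
#' Provenance metadata is stored in leading `#key=value` comment lines and
#' round-trips losslessly.
#'
#' @param trace A `fret_trace` (or plain data.frame with the schema above).
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `fret_trace`.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(trace, "meta")
  if (!is.null(meta)) write_meta_lines(con, meta)
  utils::write.table(as.data.frame(trace), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param crosstalk Crosstalk fraction applied when efficiency must be
#'   computed from donor/acceptor columns.
#' @export
read_trace <- function(path, crosstalk = 0) {
  meta <- read_meta_lines(path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed trace file '", path, "': ",
                             conditionMessage(e)))
  if (!"time_s" %in% names(df)) stop("trace file misses required column time_s")
  if (!"fret" %in% names(df)) {
    if (!all(c("donor", "acceptor") %in% names(df))) {
      stop("trace file needs either a 'fret' or 'donor'+'acceptor' columns")
    }
    df$fret <- compute_fret(df$donor, df$acceptor, crosstalk)
  }
  bad <- which(!is.finite(df$time_s))
  if (length(bad) > 0L) {
    stop("non-numeric time values at data rows: ", paste(bad, collapse = ", "))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("time column must be strictly increasing in '", path, "'")
  }
  attr(df, "meta") <- meta
  class(df) <- c("fret_trace", "data.frame")
  df
}

#' Write / read a per-trace velocity dataset
#'
#' CSV with header `mg_mM,velocity_nt_s,trace_id`. Aggregates (mean, SEM)
#' are never stored; they are recomputed via [aggregate_velocity()].
#'
#' @param data A `velocity_dataset`.
#' @param path File path.
#' @export
write_velocity_dataset <- function(data, path) {
  stopifnot(all(c("mg_mM", "velocity_nt_s", "trace_id") %in% names(data)))
  utils::write.csv(as.data.frame(data)[c("mg_mM", "velocity_nt_s", "trace_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_velocity_dataset
#' @export
read_velocity_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mg_mM", "velocity_nt_s", "trace_id")
  if (!all(need %in% names(df))) {
    stop("velocity dataset must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$mg_mM) | !is.finite(df$velocity_nt_s) |
                 df$mg_mM < 0 | df$velocity_nt_s <= 0)
  if (length(bad) > 0L) {
    stop("invalid concentration/velocity at data rows: ",
         paste(bad, collapse = ", "))
  }
  class(df) <- c("velocity_dataset", "data.frame")
  df
}

#' Write a first-passage density as two-column TSV
#'
#' The first column is named after the space (`tau_s` or `log10_v`), the
#' second is `density`.
#'
#' @param pdf An `fp_pdf`.
#' @param path File path.
#' @export
write_fp_pdf <- function(pdf, path) {
  stopifnot(inherits(pdf, "fp_pdf"))
  df <- data.frame(x = pdf$x, density = pdf$density)
  names(df)[1L] <- pdf$space
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(pdf$meta)) write_meta_lines(con, pdf$meta)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
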