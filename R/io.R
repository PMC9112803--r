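#' Read chevron datasets from CSV
#'
#' Long-format CSV with required columns `variant`, `urea_M`, `kobs_s1` and
#' an optional `sigma` column; any additional columns are carried along in
#' each dataset's `points` data.frame so that a write/read cycle is
#' lossless.
#'
#' @param path File path.
#' @return Named list of [chevron_dataset]s, in order of first appearance.
#' @export
read_chevron_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  required <- c("variant", "urea_M", "kobs_s1")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- intersect(c("urea_M", "kobs_s1", "sigma"), names(raw))
  for (cc in num_cols) {
    blank <- !nzchar(trimws(raw[[cc]]))
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !blank)
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                   cc, bad[1] + 1L, path), call. = FALSE)
    raw[[cc]] <- v
  }
  ids <- unique(raw$variant)
  out <- lapply(ids, function(id) {
    d <- raw[raw$variant == id, , drop = FALSE]
    sig <- if ("sigma" %in% names(d) && all(is.finite(d$sigma)) &&
               all(d$sigma > 0)) d$sigma else NULL
    cd <- chevron_dataset(id, d$urea_M, d$kobs_s1, sig)
    extra <- setdiff(names(d), c("variant", "urea_M", "kobs_s1", "sigma"))
    if (length(extra)) cd$points <- cbind(cd$points, d[, extra, drop = FALSE],
                                          row.names = NULL)
    cd
  })
  names(out) <- ids
  out
}

#' Write chevron datasets to CSV
#'
#' Inverse of [read_chevron_csv()]; numeric values are written with 12
#' significant digits, and any extra point columns are preserved.
#'
#' @param datasets List of [chevron_dataset]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chevron_csv <- function(datasets, path) {
  stopifnot(is.list(datasets),
            all(vapply(datasets, inherits, logical(1), "chevron_dataset")))
  rows <- lapply(datasets, function(d) {
    pts <- d$points
    base <- data.frame(variant = d$variant_id,
                       urea_M = fmt12(pts$urea), kobs_s1 = fmt12(pts$kobs),
                       sigma = ifelse(is.na(pts$sigma), "", fmt12(pts$sigma)))
    extra <- setdiff(names(pts), c("urea", "kobs", "sigma"))
    if (length(extra)) base <- cbind(base, pts[, extra, drop = FALSE])
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Load the packaged reference kinetic-parameter table
#'
#' The published per-variant folding parameters of the C-terminal SH2 domain
#' of SHP2 (wild type plus 29 conservative-truncation variants): folding and
#' unfolding rate constants, partitioning constant, mutational free-energy
#' changes and Phi-values, each with its printed uncertainty. Variants whose
#' stability change was too small for a reliable Phi-value
#' (`|ddG_eq| < 0.4` kcal mol^-1) carry `NA` Phi columns, mirroring the
#' published footnote. Values are transcribed verbatim (minus signs
#' normalised to ASCII); a checksum guards the transcription against
#' accidental edits.
#'
#' @return A data.frame of class `table1_fixture`: columns `variant`, `kf`,
#'   `kf_err`, `ku`, `ku_err`, `kpart`, `kpart_err`, `ddG_TS1N`,
#'   `ddG_TS1N_err`, `ddG_TS2N`, `ddG_TS2N_err`, `ddG_eq`, `ddG_eq_err`,
#'   `phi_ts1`, `phi_ts1_err`, `phi_ts2`, `phi_ts2_err`, `excluded`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_csh2.csv", package = "chevronfit",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  num <- unlist(tab[vapply(tab, is.numeric, logical(1))])
  if (nrow(tab) != 30L || tab$variant[1] != "wt" ||
      abs(sum(num, na.rm = TRUE) - 5781.091) > 1e-6)
    stop("integrity error: packaged reference table is corrupted",
         call. = FALSE)
  tab$excluded <- is.na(tab$phi_ts1) & tab$variant != "wt"
  class(tab) <- c("table1_fixture", "data.frame")
  tab
}

#' Kinetic parameters from a reference-table row
#'
#' Builds a [kinetic_params] object from the packaged table's printed rate
#' constants for one variant. The table does not print m-values (they were
#' shared in the published global fit), so the reference wild-type m-values
#' are attached; they do not enter any `ddG`/Phi arithmetic, which uses only
#' the rates.
#'
#' @param tab A `table1_fixture` from [load_table1()].
#' @param variant Variant id, e.g. `"wt"` or `"L117A"`.
#' @param RT Thermal energy, kcal mol^-1.
#' @return A [kinetic_params] object.
#' @export
table1_params <- function(tab, variant, RT = RT_25C) {
  stopifnot(inherits(tab, "table1_fixture"))
  row <- tab[tab$variant == variant, ]
  if (nrow(row) != 1L)
    stop("variant '", variant, "' not found in reference table", call. = FALSE)
  ref <- reference_wt_params(RT)
  kinetic_params(row$kf, ref$mf, row$ku, ref$mu, row$kpart, ref$mpart, RT = RT)
}

#' Reproduce the reference table from its own printed rate constants
#'
#' For every mutant row, recomputes from the printed `kf`, `ku`, `kpart`
#' (and the printed `ddG_eq` as the Phi normaliser):
#' `ddG_TS1N = RT*ln(ku_mut/ku_wt)`,
#' `ddG_TS2N = RT*ln((ku/kpart)_mut/(ku/kpart)_wt)`,
#' `phi_ts1 = RT*ln(kf_wt/kf_mut)/ddG_eq`, and
#' `phi_ts2 = 1 - ddG_TS2N/ddG_eq`, and compares each against the printed
#' column within the printed uncertainty, floored at `tol_ddg_floor` for
#' free energies and `tol_phi_floor` for Phi-values. Because the printed
#' rate constants are rounded to 1-2 significant figures while some printed
#' uncertainties are as small as 0.01, a few rows cannot be reproduced
#' within their printed error from the printed rates alone; these appear
#' with `FALSE` flags rather than being silently dropped.
#'
#' @param tab A `table1_fixture` (default [load_table1()]).
#' @param RT Thermal energy, kcal mol^-1.
#' @param tol_phi_floor,tol_ddg_floor Tolerance floors (0.05 and 0.1).
#' @return Data.frame with one row per mutant: recomputed values, absolute
#'   deviations, per-quantity pass flags (`NA` for excluded rows' Phi), and
#'   an overall `pass` flag.
#' @export
validate_table1 <- function(tab = load_table1(), RT = RT_25C,
                            tol_phi_floor = 0.05, tol_ddg_floor = 0.1) {
  stopifnot(inherits(tab, "table1_fixture"))
  wt <- tab[tab$variant == "wt", ]
  m <- tab[tab$variant != "wt", ]
  dT1 <- RT * log(m$ku / wt$ku)
  dT2 <- RT * log((m$ku / m$kpart) / (wt$ku / wt$kpart))
  p1 <- RT * log(wt$kf / m$kf) / m$ddG_eq
  p2 <- 1 - dT2 / m$ddG_eq
  ok <- function(val, printed, err, floor)
    abs(val - printed) <= pmax(err, floor)
  res <- data.frame(
    variant = m$variant, excluded = m$excluded,
    ddG_TS1N_calc = dT1, ddG_TS1N_ok = ok(dT1, m$ddG_TS1N, m$ddG_TS1N_err,
                                          tol_ddg_floor),
    ddG_TS2N_calc = dT2, ddG_TS2N_ok = ok(dT2, m$ddG_TS2N, m$ddG_TS2N_err,
                                          tol_ddg_floor),
    phi_ts1_calc = ifelse(m$excluded, NA_real_, p1),
    phi_ts1_ok = ok(p1, m$phi_ts1, m$phi_ts1_err, tol_phi_floor),
    phi_ts2_calc = ifelse(m$excluded, NA_real_, p2),
    phi_ts2_ok = ok(p2, m$phi_ts2, m$phi_ts2_err, tol_phi_floor))
  res$pass <- res$ddG_TS1N_ok & res$ddG_TS2N_ok &
    (m$excluded | (res$phi_ts1_ok & res$phi_ts2_ok))
  rownames(res) <- NULL
  res
}

#' Per-residue Phi category table
#'
#' Extracts the residue number from each variant id (construct numbering,
#' e.g. `V148A` -> 148) and pairs it with the Phi category of the requested
#' transition state — the plot-ready input for colouring categories onto a
#' structure with external tools.
#'
#' @param thermo A [phi_table()]-style data.frame.
#' @param which_ts `"ts1"` or `"ts2"`.
#' @return Data.frame with `residue` and `category`.
#' @export
residue_categories <- function(thermo, which_ts = c("ts1", "ts2")) {
  which_ts <- match.arg(which_ts)
  res <- suppressWarnings(as.integer(sub("^[A-Za-z]+([0-9]+).*$", "\\1",
                                         thermo$variant)))
  data.frame(residue = res,
             category = thermo[[paste0("category_", which_ts)]])
}

#' Write a global fit result as JSON
#'
#' Serialises the constraint scheme, shared m-values, per-variant parameter
#' table with standard errors, and fit diagnostics.
#'
#' @param result A `global_fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_global_fit_json <- function(result, path) {
  stopifnot(inherits(result, "global_fit_result"))
  per <- do.call(rbind, lapply(names(result$per_variant), function(id) {
    p <- result$per_variant[[id]]
    data.frame(variant = id, kf0 = p$kf0, mf = p$mf, ku0 = p$ku0, mu = p$mu,
               Kpart = p$Kpart, mpart = p$mpart)
  }))
  jsonlite::write_json(
    list(scheme = result$scheme, shared = as.list(result$shared),
         per_variant = per, standard_errors = result$standard_errors,
         objective = result$objective, converged = result$converged,
         n_points = result$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stopped-flow traces from CSV
#'
#' Two dialects are accepted: a single-trace file with columns `time_s`,
#' `fluorescence` preceded by metadata comment lines `# variant=<id>` and
#' `# urea_M=<value>`; or a long-format file with columns `trace_id`,
#' `variant`, `urea_M`, `time_s`, `fluorescence` holding many traces.
#'
#' @param path File path.
#' @return List of unfitted [trace_record]s.
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    hdr <- grep("^#", readLines(path), value = TRUE)
    meta <- function(key) {
      ln <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
      if (!length(ln))
        stop("schema error: missing '# ", key, "=' metadata line",
             call. = FALSE)
      trimws(sub("^[^=]*=", "", ln[1]))
    }
    d <- utils::read.csv(path, comment.char = "#")
    if (!all(c("time_s", "fluorescence") %in% names(d)))
      stop("schema error: trace file needs columns time_s, fluorescence",
           call. = FALSE)
    return(list(trace_record(meta("variant"), as.numeric(meta("urea_M")),
                             d$time_s, d$fluorescence)))
  }
  d <- utils::read.csv(path)
  need <- c("trace_id", "variant", "urea_M", "time_s", "fluorescence")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lapply(split(d, d$trace_id), function(g)
    trace_record(as.character(g$variant[1]), g$urea_M[1], g$time_s,
                 g$fluorescence))
}

#' Write traces to a long-format CSV
#'
#' @param traces List of [trace_record]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, logical(1), "trace_record")))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(trace_id = i, variant = tr$variant_id, urea_M = tr$urea,
               time_s = fmt12(tr$times), fluorescence = fmt12(tr$fluorescence))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
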