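#' Write a simulated scenario (or waveform set) to CSV
#'
#' Writes columns `time_s`, `rvp_mmHg`, `pap_mmHg`, `aof_mL_s`,
#' `vol_mL`, preceded by commented header lines (`# key=value`)
#' carrying the sampling rate, seed and ground-truth generative
#' parameters, so a recording round-trips losslessly with its
#' provenance.
#'
#' @param scenario an `elastance_scenario` from [simulate_beats()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_waveforms <- function(scenario, path) {
  stopifnot(inherits(scenario, "elastance_scenario"))
  p <- scenario$params; a <- scenario$afterload; cf <- scenario$config
  hdr <- c(
    sprintf("# fs=%g", cf$fs),
    sprintf("# seed=%d", cf$seed),
    sprintf("# emax=%g emin=%g v0=%g ved=%g hr=%g", p$emax, p$emin,
            p$v0, p$ved, p$hr),
    sprintf("# zc=%g rp=%g c_art=%g pd0=%g", a$zc, a$rp, a$c_art, a$pd0),
    sprintf("# noise_sd=%g resp_amp=%g", cf$noise_sd, cf$resp_amp),
    "# units: time_s=s rvp_mmHg=mmHg pap_mmHg=mmHg aof_mL_s=mL/s vol_mL=mL"
  )
  fmt <- function(x) sprintf("%.17g", x)   # lossless numeric round trip
  df <- data.frame(time_s = fmt(scenario$rvp$t),
                   rvp_mmHg = fmt(scenario$rvp$y),
                   pap_mmHg = fmt(scenario$pap$y),
                   aof_mL_s = fmt(scenario$flow$y),
                   vol_mL = fmt(scenario$volume$y))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform CSV into waveform objects
#'
#' Expects the format written by [write_waveforms()]: commented
#' `# key=value` header lines (at minimum `fs`), then a `time_s` column
#' plus named signal columns with unit suffixes (`_mmHg`, `_mL_s`,
#' `_mL`). The time grid must be uniform; the header sampling rate must
#' agree with the grid spacing.
#'
#' @param path CSV path.
#' @param tol relative tolerance for grid uniformity and fs agreement.
#' @return list of [waveform()]s (named by signal), plus `meta` (parsed
#'   header key-values).
#' @export
read_waveforms <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, gregexpr("[A-Za-z_0-9]+=[-0-9.eE+]+", h))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=")[[1]]
      meta[[parts[1]]] <- as.numeric(parts[2])
    }
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  dt <- diff(df$time_s)
  if (length(dt) < 1) stop("waveform file holds fewer than 2 samples")
  if ((max(dt) - min(dt)) > tol * stats::median(dt))
    stop(sprintf("non-uniform time grid: max gap %.6g s vs median %.6g s",
                 max(dt), stats::median(dt)))
  fs_inferred <- 1 / stats::median(dt)
  fs <- meta$fs
  if (is.null(fs)) {
    fs <- fs_inferred
  } else if (abs(fs - fs_inferred) > tol * fs) {
    stop(sprintf("header fs=%g Hz disagrees with time-grid spacing (%g Hz)",
                 fs, fs_inferred))
  }
  unit_map <- c(mmHg = "mmHg", mL_s = "mL/s", mL = "mL")
  sig_cols <- setdiff(names(df), "time_s")
  out <- list()
  for (col in sig_cols) {
    suffix <- sub("^.*?_(mmHg|mL_s|mL)$", "\\1", col)
    if (!suffix %in% names(unit_map))
      stop(sprintf("unknown unit label on column '%s'", col))
    label <- sub(sprintf("_%s$", suffix), "", col)
    out[[label]] <- waveform(df[[col]], fs, label, unit_map[[suffix]],
                             t0 = df$time_s[1])
  }
  out$meta <- meta
  out
}

#' Write Ct records to TSV / read them back
#'
#' @param records data frame of Ct records (`sample_id`, `group`,
#'   `gene`, `ct`).
#' @param path TSV path.
#' @return the path (write) or the data frame (read).
#' @export
write_ct_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an analysis report for a cohort
#'
#' Emits a machine-readable TSV of per-animal coupling summaries and a
#' human-readable text summary laid out per variable as rest/exercise
#' by group, plus a provenance block (package version, seed, config
#' hash).
#'
#' @param results data frame with one row per animal x condition:
#'   columns `id`, `group`, `condition`, `n_beats_used`, `median_pmax`,
#'   `median_ees`, `median_ea`, `median_ratio`.
#' @param dir output directory (created if needed).
#' @param seed the seed the run used (recorded in provenance).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(results, dir, seed = NA_integer_) {
  stopifnot(is.data.frame(results))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "coupling_summary.tsv")
  utils::write.table(results, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  txt <- file.path(dir, "summary.txt")
  vars <- intersect(c("median_pmax", "median_ees", "median_ea",
                      "median_ratio"), names(results))
  lines <- c("RV-PA coupling summary (group means of per-animal medians)",
             "")
  for (v in vars) {
    lines <- c(lines, v)
    tab <- tapply(results[[v]],
                  list(results$group, results$condition), mean)
    for (g in rownames(tab)) {
      lines <- c(lines, sprintf("  %-8s %s", g,
                                paste(sprintf("%s=%.3f", colnames(tab),
                                              tab[g, ]),
                                      collapse = "  ")))
    }
    lines <- c(lines, "")
  }
  cfg_str <- paste(utils::capture.output(utils::str(results)),
                   collapse = "\n")
  tmp <- tempfile(); writeLines(cfg_str, tmp)
  lines <- c(lines, "provenance:",
             sprintf("  package_version=%s",
                     as.character(utils::packageVersion("rvpac"))),
             sprintf("  seed=%s", seed),
             sprintf("  config_hash=%s", unname(tools::md5sum(tmp))))
  unlink(tmp)
  writeLines(lines, txt)
  invisible(c(tsv, txt))
}

#' Run the full synthetic-cohort demonstration workflow
#'
#' One call exercising every pipeline stage on a seeded synthetic
#' cohort: generate paired rest/exercise recordings for a control and a
#' CTEPH arm, run the single-beat coupling analysis on each recording,
#' test the group x condition interaction on the coupling ratio,
#' generate and normalize a synthetic qPCR table, and write the report
#' files.
#'
#' @param out_dir output directory; NULL skips file output.
#' @param seed master seed for the whole workflow.
#' @param n_control,n_cteph animals per arm.
#' @param n_beats beats per recording.
#' @return list with `coupling` (per-animal summary data frame),
#'   `interaction` (the coupling-ratio interaction test), `expression`
#'   (qPCR group summary), and `files` written (if any).
#' @export
run_demo <- function(out_dir = NULL, seed = 1L, n_control = 7,
                     n_cteph = 7, n_beats = 15) {
  cohort <- generate_cohort(n_control = n_control, n_cteph = n_cteph,
                            seed = seed, n_beats = n_beats)
  rows <- list()
  for (id in cohort$meta$id) {
    bw <- cohort$meta$bw[cohort$meta$id == id]
    for (cond in c("rest", "exercise")) {
      sc <- cohort$scenarios[[id]][[cond]]
      cs <- analyze_coupling(sc$rvp, sc$pap, sc$flow, bw = bw)
      rows[[paste(id, cond)]] <- data.frame(
        id = id, group = cohort$meta$group[cohort$meta$id == id],
        condition = cond, n_beats_used = cs$n_beats_used,
        median_pmax = cs$median_pmax, median_ees = cs$median_ees,
        median_ea = cs$median_ea, median_ratio = cs$median_ratio)
    }
  }
  coupling <- do.call(rbind, rows)
  rownames(coupling) <- NULL

  inter <- interaction_permutation_test(
    coupling$median_ratio, coupling$group, coupling$condition,
    coupling$id, n_perm = 2000, seed = seed)

  ct <- generate_ct_table(ct_design(
    fold = c(bnp = 7.5, rock2 = 1.6, nox4 = 1.5, casp3 = 1.4),
    seed = seed))
  rel <- normalize_ddct(ct)
  expr <- summarize_expression(rel)

  files <- character(0)
  if (!is.null(out_dir)) {
    files <- write_report(coupling, out_dir, seed = seed)
    ct_path <- file.path(out_dir, "ct_table.tsv")
    write_ct_table(ct, ct_path)
    files <- c(files, ct_path)
  }
  list(coupling = coupling, interaction = inter, expression = expr,
       files = files)
}
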