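# Shared comparison engine: every study design reduces to a set of
# (arm A, arm B) contour-source pairs evaluated per patient and structure.
# `pairs` has columns comparison, a_observer, a_sequence, b_observer,
# b_sequence.
compute_records <- function(cohort, pairs, design, q = 95, surface = TRUE,
                            verbose = FALSE) {
  metrics <- c("dsc", "hd95", "hd", "volume_a", "volume_b")
  patients <- sort(unique(cohort$patient_id))
  structures <- intersect(oar_structures(), unique(cohort$structure))
  have <- function(pid, obs, seqn, str) {
    hit <- cohort$patient_id == pid & cohort$observer == obs &
      cohort$sequence == seqn & cohort$structure == str
    if (!any(hit)) NA_character_ else cohort_path(cohort, cohort$path[hit][1])
  }
  out <- vector("list", length(patients) * nrow(pairs) * length(structures))
  n_out <- 0L
  emit <- function(pid, str, cmp, values) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- tibble::tibble(
      patient_id = pid, structure = str, design = design, comparison = cmp,
      metric = metrics, value = values
    )
  }
  for (pid in patients) {
    if (verbose) message("  patient ", pid)
    cache <- new.env(parent = emptyenv())
    cached_load <- function(path) {
      if (!exists(path, envir = cache, inherits = FALSE)) {
        assign(path, load_label_volume(path), envir = cache)
      }
      get(path, envir = cache, inherits = FALSE)
    }
    for (r in seq_len(nrow(pairs))) {
      for (str in structures) {
        pa <- have(pid, pairs$a_observer[r], pairs$a_sequence[r], str)
        pb <- have(pid, pairs$b_observer[r], pairs$b_sequence[r], str)
        vals <- rep(NA_real_, 5L)
        if (!is.na(pa) && !is.na(pb)) {
          res <- tryCatch({
            a <- cached_load(pa)
            b <- cached_load(pb)
            pm <- pair_metrics(a, b, q = q, surface = surface)
            c(pm$dsc, pm$hd95, pm$hd, pm$volume_a, pm$volume_b)
          }, error = function(e) {
            message("not available: ", pid, " ", str, " [",
                    pairs$comparison[r], "]: ", conditionMessage(e))
            NULL
          })
          if (!is.null(res)) vals <- res
        } else {
          message("not available: ", pid, " ", str, " [",
                  pairs$comparison[r], "]: mask missing")
        }
        emit(pid, str, pairs$comparison[r], vals)
      }
    }
  }
  dplyr::bind_rows(out[seq_len(n_out)])
}

summarize_design <- function(records) {
  summary <- records |>
    dplyr::filter(.data$metric %in% c("dsc", "hd95")) |>
    summarize_mean_sd(dplyr::all_of(c("metric", "structure", "comparison"))) |>
    dplyr::select("metric", "structure", "comparison", "n", "mean", "sd",
                  "formatted")

  volume_agreement <- records |>
    dplyr::filter(.data$metric %in% c("volume_a", "volume_b")) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value") |>
    dplyr::filter(!is.na(.data$volume_a), !is.na(.data$volume_b)) |>
    dplyr::summarise(
      n = dplyr::n(),
      icc = if (dplyr::n() >= 2) {
        icc_2_1(cbind(.data$volume_a, .data$volume_b))$icc
      } else NA_real_,
      p_value = wilcoxon_rank_sum(.data$volume_a, .data$volume_b)$p_value,
      .by = c("structure", "comparison")
    ) |>
    dplyr::mutate(
      icc_good = .data$icc > 0.75,
      significant = .data$p_value < 0.05
    )
  list(summary = summary, volume_agreement = volume_agreement)
}

new_variability_result <- function(design, records) {
  s <- summarize_design(records)
  structure(
    list(design = design, records = records, summary = s$summary,
         volume_agreement = s$volume_agreement),
    class = "variability_result"
  )
}

#' @export
print.variability_result <- function(x, ...) {
  cat(sprintf("<variability_result: %s> %d records, %d patients\n",
              x$design, nrow(x$records), length(unique(x$records$patient_id))))
  print(x$summary, n = 15)
  invisible(x)
}

#' @export
tidy.variability_result <- function(x, ...) x$records

#' @export
glance.variability_result <- function(x, ...) {
  avail <- dplyr::filter(x$records, !is.na(.data$value))
  tibble::tibble(
    design = x$design,
    n_patients = length(unique(x$records$patient_id)),
    n_records = nrow(x$records),
    n_not_available = nrow(x$records) - nrow(avail),
    mean_dsc = mean(avail$value[avail$metric == "dsc"]),
    mean_hd95 = mean(avail$value[avail$metric == "hd95"])
  )
}

#' Interobserver variability over a cohort
#'
#' For every patient, sequence and structure, compares the two observers'
#' masks (DSC, undirected HD, 95% HD, volumes), then aggregates per
#' (sequence, structure): mean ± SD of the metrics, volume ICC(2,1) across
#' patients, and a Wilcoxon rank-sum p-value on the volumes. Structures
#' missing (or empty) for either observer become "not available" records —
#' reported with a reduced per-cell n, never imputed.
#'
#' @param cohort A `cohort_index` (see [read_cohort_manifest()]).
#' @param observers The two observers to compare.
#' @param q Hausdorff percentile (default 95).
#' @param surface Boundary (default) or filled voxel sets for HD.
#' @param verbose Log per-patient progress to stderr.
#' @return A `variability_result`: `$records` (long per-patient metrics),
#'   `$summary` (mean ± SD per structure and sequence) and
#'   `$volume_agreement` (ICC and p per structure and sequence).
#' @export
run_interobserver <- function(cohort, observers = c("R1", "R2"), q = 95,
                              surface = TRUE, verbose = FALSE) {
  stopifnot(length(observers) == 2)
  seqs <- intersect(mr_sequences(), unique(cohort$sequence))
  seqs <- seqs[vapply(seqs, function(s) {
    all(vapply(observers, function(o) {
      any(cohort$observer == o & cohort$sequence == s)
    }, TRUE))
  }, TRUE)]
  if (!length(seqs)) stop("no sequence has both observers present")
  pairs <- tibble::tibble(
    comparison = seqs,
    a_observer = observers[1], a_sequence = seqs,
    b_observer = observers[2], b_sequence = seqs
  )
  records <- compute_records(cohort, pairs, "interobserver", q, surface, verbose)
  new_variability_result("interobserver", records)
}

sequence_pairs <- function(seqs) {
  # canonical study order: T1WI-T1dixonc, T1WI-T2WI, T2WI-T1dixonc
  canon <- list(c("T1WI", "T1dixonc"), c("T1WI", "T2WI"), c("T2WI", "T1dixonc"))
  keep <- Filter(function(p) all(p %in% seqs), canon)
  if (!length(keep)) stop("fewer than two sequences available")
  tibble::tibble(
    a_sequence = vapply(keep, `[`, "", 1L),
    b_sequence = vapply(keep, `[`, "", 2L)
  )
}

#' Intersequence variability for one observer
#'
#' Compares one observer's contours across MR sequence pairs
#' (T1WI–T1dixonc, T1WI–T2WI, T2WI–T1dixonc) per patient and structure, and
#' aggregates exactly like [run_interobserver()]. The resulting summary has
#' the canonical layout of per-structure rows by sequence-pair columns.
#'
#' @inheritParams run_interobserver
#' @param observer Whose contours to compare across sequences.
#' @return A `variability_result`.
#' @export
run_intersequence <- function(cohort, observer = "R2", q = 95, surface = TRUE,
                              verbose = FALSE) {
  seqs <- intersect(mr_sequences(),
                    unique(cohort$sequence[cohort$observer == observer]))
  if (length(seqs) < 2) stop("observer '", observer,
                             "' is present on fewer than 2 sequences")
  sp <- sequence_pairs(seqs)
  pairs <- tibble::tibble(
    comparison = paste0(sp$a_sequence, "-", sp$b_sequence),
    a_observer = observer, a_sequence = sp$a_sequence,
    b_observer = observer, b_sequence = sp$b_sequence
  )
  records <- compute_records(cohort, pairs, "intersequence", q, surface, verbose)
  new_variability_result("intersequence", records)
}

#' Automatic-versus-manual variability
#'
#' Compares the automatic observer's contours against each human observer on
#' every shared sequence, and additionally the automatic contours across
#' sequence pairs (the automatic intersequence design). Both human
#' comparisons are emitted — when the humans disagree there is no single
#' ground truth, so results are reported against each. If the automatic
#' observer is absent the function errors; if it is absent on some sequence
#' those comparisons are skipped with a warning.
#'
#' @inheritParams run_interobserver
#' @param auto Label of the automatic observer.
#' @param observers Human observer labels.
#' @return A named list of `variability_result`s: one `auto_vs_<observer>`
#'   per human observer and one `auto_intersequence`.
#' @export
run_auto_vs_manual <- function(cohort, auto = "AUTO",
                               observers = c("R1", "R2"), q = 95,
                               surface = TRUE, verbose = FALSE) {
  if (!any(cohort$observer == auto)) {
    stop("automatic observer '", auto, "' not present in cohort")
  }
  auto_seqs <- intersect(mr_sequences(),
                         unique(cohort$sequence[cohort$observer == auto]))
  missing_seqs <- setdiff(intersect(mr_sequences(), unique(cohort$sequence)),
                          auto_seqs)
  if (length(missing_seqs)) {
    warning("automatic observer missing on sequence(s) ",
            paste(missing_seqs, collapse = ", "), "; skipped")
  }
  out <- list()
  for (obs in observers) {
    seqs <- intersect(auto_seqs,
                      unique(cohort$sequence[cohort$observer == obs]))
    if (!length(seqs)) {
      warning("no shared sequence between ", auto, " and ", obs, "; skipped")
      next
    }
    pairs <- tibble::tibble(
      comparison = seqs,
      a_observer = auto, a_sequence = seqs,
      b_observer = obs, b_sequence = seqs
    )
    design <- paste0("auto_vs_", obs)
    records <- compute_records(cohort, pairs, design, q, surface, verbose)
    out[[design]] <- new_variability_result(design, records)
  }
  if (length(auto_seqs) >= 2) {
    out$auto_intersequence <- run_intersequence(cohort, observer = auto, q = q,
                                                surface = surface,
                                                verbose = verbose)
    out$auto_intersequence$design <- "auto_intersequence"
    out$auto_intersequence$records$design <- "auto_intersequence"
  }
  out
}

#' Write report tables for one or more designs
#'
#' Writes, per design, a summary CSV (`metric,structure,comparison,n,mean,
#' sd,formatted`) and a volume-agreement CSV (ICC and Wilcoxon p per
#' structure and comparison), plus one long-format `records.csv` across all
#' designs and a `manifest.json` recording the configuration, seed, package
#' version and input file checksums, so a run can be reproduced and audited.
#'
#' @param results A `variability_result` or a (possibly named) list of them.
#' @param out_dir Output directory, created if needed.
#' @param cohort Optional `cohort_index`; when given, input file MD5
#'   checksums are recorded in the manifest.
#' @param config Optional list of run settings to store in the manifest.
#' @param seed Optional seed to store in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, cohort = NULL, config = list(),
                         seed = NULL) {
  if (inherits(results, "variability_result")) results <- list(results)
  if (!length(results)) stop("no result tables to write")
  bad <- !vapply(results, inherits, TRUE, "variability_result")
  if (any(bad)) stop("`results` must contain variability_result objects")
  nm <- names(results)
  if (is.null(nm)) nm <- rep("", length(results))
  nm[nm == ""] <- vapply(results[nm == ""], function(r) r$design, "")
  names(results) <- nm

  all_records <- dplyr::bind_rows(lapply(results, function(r) r$records))
  if (!nrow(all_records)) stop("results contain no records; nothing to write")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  paths <- character()
  for (n in names(results)) {
    p1 <- file.path(out_dir, paste0(n, "_summary.csv"))
    readr::write_csv(results[[n]]$summary, p1)
    p2 <- file.path(out_dir, paste0(n, "_volume_agreement.csv"))
    readr::write_csv(results[[n]]$volume_agreement, p2)
    paths <- c(paths, p1, p2)
  }
  prec <- file.path(out_dir, "records.csv")
  readr::write_csv(all_records, prec)

  manifest <- list(
    package = "contourvar",
    version = as.character(utils::packageVersion("contourvar")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    designs = names(results)
  )
  if (!is.null(cohort)) {
    files <- cohort_path(cohort, cohort$path)
    ok <- file.exists(files)
    manifest$input_checksums <- stats::setNames(
      as.list(unname(tools::md5sum(files[ok]))), cohort$path[ok]
    )
  }
  pman <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, pman, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(c(paths, prec, pman))
}
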