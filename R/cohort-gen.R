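#' Perturbation presets for synthetic cohorts
#'
#' Named bundles of observer models and per-sequence noise multipliers that
#' emulate the qualitative structure of a contouring variability study:
#'
#' * `"clean"` — all models zero; every comparison should be perfect
#'   agreement (useful as an end-to-end identity check).
#' * `"paper_like"` — two human observers with moderate, comparable noise,
#'   an automatic observer (`AUTO`) with its own profile (best on T2WI,
#'   worst on T1dixonc), and sequence multipliers making T1dixonc the
#'   noisiest sequence while T1WI and T2WI are comparable — so the
#'   T1WI–T2WI pair is the most similar, the pattern reported in MR pelvic
#'   contouring studies.
#' * `"heavy_noise"` — the paper_like profile with all SDs doubled.
#'
#' @param preset One of `"paper_like"`, `"clean"`, `"heavy_noise"`.
#' @return List with elements `observer_models` (named list of
#'   [perturbation_model()]) and `sequence_multipliers` (named numeric).
#' @export
perturbation_preset <- function(preset = c("paper_like", "clean", "heavy_noise")) {
  preset <- match.arg(preset)
  if (preset == "clean") {
    zero <- perturbation_model()
    return(list(
      observer_models = list(R1 = zero, R2 = zero, AUTO = zero),
      sequence_multipliers = c(T1WI = 1, T1dixonc = 1, T2WI = 1)
    ))
  }
  s <- if (preset == "heavy_noise") 2 else 1
  list(
    observer_models = list(
      R1 = perturbation_model(translation_sd = 0.8 * s, boundary_sd = 1.2 * s),
      R2 = perturbation_model(translation_sd = 0.8 * s, boundary_sd = 1.2 * s,
                              dilation_bias = 0.3),
      AUTO = perturbation_model(
        translation_sd = 1.0 * s, boundary_sd = 2.0 * s,
        dilation_bias = -0.3,
        seq_multipliers = c(T1WI = 1.0, T1dixonc = 1.6, T2WI = 0.7)
      )
    ),
    sequence_multipliers = c(T1WI = 1.0, T1dixonc = 1.5, T2WI = 1.0)
  )
}

#' Generate a synthetic multi-observer, multi-sequence cohort
#'
#' Writes NIfTI masks and a manifest CSV for every (patient, observer,
#' sequence, structure) combination. Each patient's ground truth is built
#' by [generate_base_patient()]; each observer x sequence combination
#' applies the observer's [perturbation_model()], scaled by that sequence's
#' noise multiplier, independently per structure. The ground truth is also
#' written under observer `"GT"` for every sequence. Generation is a pure
#' function of `(params, models, seed)`: seeds are split hierarchically per
#' patient/observer/sequence/structure, so adding patients never reshuffles
#' existing ones.
#'
#' @param n_patients Number of patients (the study-like default is 29, the
#'   size of a typical testing cohort).
#' @param params [phantom_params()].
#' @param observer_models Named list of [perturbation_model()]s (e.g. from
#'   [perturbation_preset()]).
#' @param sequence_multipliers Named numeric over `mr_sequences()`; scales
#'   each observer's random components per sequence unless the observer
#'   model carries its own `seq_multipliers`.
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param sequences Which sequences to generate.
#' @return The cohort's `cohort_index` (also written as `manifest.csv`).
#' @export
generate_cohort <- function(n_patients = 29L,
                            params = phantom_params(),
                            observer_models = perturbation_preset("paper_like")$observer_models,
                            sequence_multipliers = perturbation_preset("paper_like")$sequence_multipliers,
                            out_dir,
                            seed = 1L,
                            sequences = mr_sequences()) {
  stopifnot(n_patients >= 1, length(observer_models) >= 1,
            length(sequences) >= 1)
  check_sequence(sequences)
  if (is.null(names(observer_models)) || any(names(observer_models) == "")) {
    stop("`observer_models` must be a named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  rows <- list()
  add_row <- function(pid, obs, seqn, str, rel) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      patient_id = pid, observer = obs, sequence = seqn, structure = str,
      path = rel
    )
  }
  write_mask <- function(v, pid, obs, seqn, str) {
    rel <- file.path(pid, obs, seqn, paste0(str, ".nii.gz"))
    abs <- file.path(out_dir, rel)
    dir.create(dirname(abs), recursive = TRUE, showWarnings = FALSE)
    write_label_volume(v, abs)
    add_row(pid, obs, seqn, str, rel)
  }

  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    gt <- generate_base_patient(params, patient_seed = split_seed(seed, pid, "GT"),
                                patient_id = pid)
    for (seqn in sequences) {
      for (str in names(gt$masks)) {
        write_mask(gt$masks[[str]], pid, "GT", seqn, str)
      }
      for (obs in names(observer_models)) {
        model <- observer_models[[obs]]
        mult <- if (!is.null(model$seq_multipliers)) {
          model$seq_multipliers[[seqn]]
        } else if (seqn %in% names(sequence_multipliers)) {
          sequence_multipliers[[seqn]]
        } else 1
        scaled <- scale_model(model, mult)
        for (str in names(gt$masks)) {
          pm <- perturb(gt$masks[[str]], scaled,
                        seed = split_seed(seed, pid, obs, seqn, str))
          write_mask(pm, pid, obs, seqn, str)
        }
      }
    }
  }
  entries <- dplyr::bind_rows(rows)
  readr::write_csv(entries, file.path(out_dir, "manifest.csv"))
  new_cohort_index(entries, root = out_dir)
}
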