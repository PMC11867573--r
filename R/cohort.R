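#' Structure and sequence vocabularies
#'
#' The five pelvic organs at risk handled by the pipeline, and the three MR
#' sequences contours are drawn on. All cohort-facing functions validate
#' against these sets.
#'
#' @return Character vector of canonical names.
#' @export
oar_structures <- function() {
  c("bladder", "rectum", "anal_canal", "femoral_head_L", "femoral_head_R")
}

#' @rdname oar_structures
#' @export
mr_sequences <- function() {
  c("T1WI", "T1dixonc", "T2WI")
}

check_structure <- function(structure) {
  bad <- setdiff(structure, oar_structures())
  if (length(bad)) {
    stop("unknown structure(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(oar_structures(), collapse = ", "), ")")
  }
  invisible(structure)
}

check_sequence <- function(sequence) {
  bad <- setdiff(sequence, mr_sequences())
  if (length(bad)) {
    stop("unknown sequence(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(mr_sequences(), collapse = ", "), ")")
  }
  invisible(sequence)
}

#' Bundle one observer's structures on one sequence
#'
#' A contour set collects the masks one observer delineated on one MR
#' sequence for one patient. All member volumes must share a single grid
#' (spacing, origin, shape): they come from the same image.
#'
#' @param patient_id,observer Character scalars.
#' @param sequence One of `mr_sequences()`.
#' @param masks Named list of [label_volume()]s; names from
#'   `oar_structures()`.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(patient_id, observer, sequence, masks) {
  check_sequence(sequence)
  check_structure(names(masks))
  if (length(masks)) {
    ref <- masks[[1]]
    for (m in masks) validate_comparable(ref, m)
  }
  structure(
    list(patient_id = patient_id, observer = observer, sequence = sequence,
         masks = masks),
    class = "contour_set"
  )
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> patient %s, observer %s, sequence %s: %s\n",
              x$patient_id, x$observer, x$sequence,
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

new_cohort_index <- function(entries, root) {
  entries <- tibble::as_tibble(entries)
  needed <- c("patient_id", "observer", "sequence", "structure", "path")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols)) {
    stop("cohort manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries <- dplyr::mutate(entries, dplyr::across(dplyr::all_of(needed), as.character))
  key <- paste(entries$patient_id, entries$observer, entries$sequence,
               entries$structure)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, observer, sequence, structure) entries in cohort")
  }
  check_sequence(unique(entries$sequence))
  check_structure(unique(entries$structure))
  out <- entries[needed]
  attr(out, "root") <- root
  class(out) <- c("cohort_index", class(out))
  out
}

#' Read a cohort manifest
#'
#' A cohort is indexed by a CSV manifest with columns
#' `patient_id,observer,sequence,structure,path` (paths relative to the
#' manifest's directory, or absolute). Alternatively,
#' [discover_cohort()] builds the same index from a
#' `root/<patient>/<observer>/<sequence>/<structure>.nii.gz` layout.
#'
#' @param path Path to the manifest CSV.
#' @return A `cohort_index`: a tibble with one row per mask file.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  entries <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  new_cohort_index(entries, root = dirname(path))
}

#' @rdname read_cohort_manifest
#' @param root Cohort root directory for layout auto-discovery.
#' @export
discover_cohort <- function(root) {
  if (!dir.exists(root)) stop("cohort root not found: ", root)
  files <- list.files(root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE)
  parts <- strsplit(files, "/", fixed = TRUE)
  keep <- vapply(parts, length, 1L) == 4L
  parts <- parts[keep]
  files <- files[keep]
  if (!length(files)) stop("no masks found under ", root)
  entries <- tibble::tibble(
    patient_id = vapply(parts, `[`, "", 1L),
    observer = vapply(parts, `[`, "", 2L),
    sequence = vapply(parts, `[`, "", 3L),
    structure = sub("\\.nii(\\.gz)?$", "", vapply(parts, `[`, "", 4L)),
    path = files
  )
  new_cohort_index(entries, root = root)
}

cohort_path <- function(cohort, path) {
  root <- attr(cohort, "root")
  ifelse(is.na(path) | path == "" | grepl("^(/|[A-Za-z]:)", path),
         path, file.path(root, path))
}

#' Load one observer's contour set from a cohort
#'
#' @param cohort A `cohort_index`.
#' @param patient_id,observer,sequence Which cell of the cohort to load.
#' @return A [contour_set()]; structures without a file are absent from it.
#' @export
load_contour_set <- function(cohort, patient_id, observer, sequence) {
  rows <- dplyr::filter(
    cohort,
    .data$patient_id == !!patient_id,
    .data$observer == !!observer,
    .data$sequence == !!sequence
  )
  masks <- lapply(cohort_path(cohort, rows$path), load_label_volume)
  names(masks) <- rows$structure
  contour_set(patient_id, observer, sequence, masks)
}
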