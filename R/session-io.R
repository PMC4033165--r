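#' Write a session to disk
#'
#' Writes one NIfTI-1 volume series plus one BIDS-like events file per run
#' (tab-separated columns `onset`, `duration`, `state`) and a JSON sidecar
#' holding the repetition time and the session seed, so the session can be
#' re-read or regenerated exactly.
#'
#' @param session A `percept_session`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, a tibble of the paths written (`run`, `nifti`,
#'   `events`).
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "percept_session"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- purrr::map_dfr(session$runs, function(run) {
    nii <- file.path(directory, sprintf("run-%02d_bold.nii.gz", run$run_id))
    ev <- file.path(directory, sprintf("run-%02d_events.tsv", run$run_id))
    tryCatch({
      RNifti::writeNifti(RNifti::asNifti(run$data), nii)
      readr::write_tsv(tibble::as_tibble(run$timeline)[, c("onset", "duration", "state")], ev)
    }, error = function(e)
      stop("failed writing run ", run$run_id, " under ", directory, ": ",
           conditionMessage(e), call. = FALSE))
    tibble::tibble(run = run$run_id, nifti = nii, events = ev)
  })
  jsonlite::write_json(
    list(tr_s = session$tr, seed = session$seed,
         grid_shape = session$grid_shape),
    file.path(directory, "session.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Read a session written by [write_session()]
#'
#' @param directory Directory containing `run-*_bold.nii.gz`,
#'   `run-*_events.tsv` and `session.json`.
#' @return A `percept_session` (without a `voxels` specification, which is a
#'   simulation-side object).
#' @export
read_session <- function(directory) {
  side <- jsonlite::read_json(file.path(directory, "session.json"),
                              simplifyVector = TRUE)
  niis <- sort(list.files(directory, pattern = "^run-.*_bold\\.nii\\.gz$",
                          full.names = TRUE))
  if (!length(niis)) stop("no run NIfTI files under ", directory, call. = FALSE)
  runs <- purrr::map(niis, function(nii) {
    rid <- as.integer(sub("^run-([0-9]+)_bold.*$", "\\1", basename(nii)))
    ev <- file.path(directory, sprintf("run-%02d_events.tsv", rid))
    tab <- readr::read_tsv(ev, show_col_types = FALSE)
    arr <- array(as.numeric(RNifti::readNifti(nii)),
                 dim = dim(RNifti::readNifti(nii)))
    tl <- percept_timeline(tab$onset, tab$duration, tab$state,
                           total_duration = sum(tab$duration))
    structure(list(data = arr, tr = side$tr_s, run_id = rid, timeline = tl),
              class = "bold_run")
  })
  structure(
    list(runs = runs, grid_shape = as.integer(side$grid_shape),
         tr = side$tr_s, seed = side$seed, voxels = NULL),
    class = "percept_session"
  )
}
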