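#' Write MFCC spectra to a directory
#'
#' One CSV matrix per spectrum plus a `manifest.csv` (id, source
#' recording, label, shape, file).
#'
#' @param spectra List of [mfcc_spectrum] objects.
#' @param dir Output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    fname <- sprintf("%s.csv", sp$source_id)
    utils::write.table(sp$values, file.path(dir, fname), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    data.frame(id = sp$source_id,
               source = sub("_seg[0-9]+$", "", sp$source_id),
               label = sp$label, n_coeff = sp$n_coeff,
               n_frames = sp$n_frames, file = fname)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read MFCC spectra written by [write_spectra()]
#'
#' @param dir Directory containing `manifest.csv` and per-spectrum CSVs.
#' @return List of [mfcc_spectrum] objects.
#' @export
read_spectra <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    vals <- as.matrix(utils::read.table(file.path(dir, m$file), sep = ","))
    dimnames(vals) <- NULL
    stopifnot(nrow(vals) == m$n_coeff, ncol(vals) == m$n_frames)
    structure(list(values = vals, n_coeff = m$n_coeff,
                   n_frames = m$n_frames, source_id = m$id,
                   label = if (is.na(m$label)) NA else m$label),
              class = "mfcc_spectrum")
  })
}

#' Read a PhysioNet-2016-style directory of labeled recordings
#'
#' Expects a directory of `*.wav` files and a CSV of `<record>,<label>`
#' pairs (no header needed) with labels -1 (normal) and 1 (abnormal),
#' mapped here to 0/1.
#'
#' @param dir Directory containing the WAV files.
#' @param label_csv Path to the label CSV (default `dir/REFERENCE.csv`).
#' @return List of [pcg_recording] objects.
#' @export
read_physionet_dir <- function(dir, label_csv = file.path(dir, "REFERENCE.csv")) {
  labels <- utils::read.csv(label_csv, header = FALSE,
                            col.names = c("record", "label"))
  if (!all(labels$label %in% c(-1, 1)))
    stop("labels must be -1 (normal) or 1 (abnormal)")
  lapply(seq_len(nrow(labels)), function(i) {
    rec <- as.character(labels$record[i])
    w <- read_wav(file.path(dir, paste0(rec, ".wav")))
    pcg_recording(w$samples, w$sample_rate,
                  label = if (labels$label[i] == -1) 0 else 1, id = rec)
  })
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the configuration, all weights and the
#' initialization seed, so a run can be resumed or audited.
#'
#' @param model A `capsnet_model`.
#' @param path Checkpoint file path (`.rds`).
#' @return `path` (save) or the restored `capsnet_model` (load).
#' @export
save_capsnet <- function(model, path) {
  stopifnot(inherits(model, "capsnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_capsnet
#' @export
load_capsnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "capsnet_model"))
  model
}
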