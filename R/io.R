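# Readers and writers. Recordings travel as CSV (time, ch_contra,
# ch_ipsi; microvolts, input-referred) with a JSON sidecar holding the
# sample rate, units flag, stimulus onsets and protocol. Tables are
# TSV; configs are YAML; every output directory gets a checksum
# manifest.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Write a recording to CSV + JSON sidecar
#'
#' @param recording An `ecog_recording`.
#' @param path CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ecog_recording"))
  n <- length(recording$ch_contra)
  dt <- data.table::data.table(
    time = (seq_len(n) - 1) / recording$sample_rate,
    ch_contra = recording$ch_contra,
    ch_ipsi = recording$ch_ipsi
  )
  data.table::fwrite(dt, path)
  proto <- recording$protocol
  meta <- list(
    animal_id = recording$animal_id,
    sample_rate = recording$sample_rate,
    units = "uV_input_referred",
    stim_onsets = recording$stim_onsets,
    protocol = list(conc_pct = proto$conc_pct,
                    segment_minutes = (proto$end_s[1] - proto$start_s[1]) / 60)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a recording from CSV + JSON sidecar
#'
#' Validates the channel set, the input-referred units flag (data with
#' the acquisition gain still applied is rejected) and the recording
#' invariants (equal channel lengths, strictly increasing in-range
#' stimulus onsets).
#'
#' @param path CSV path written by [write_recording()].
#' @return An `ecog_recording` (without synthetic ground truth).
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$units) || meta$units != "uV_input_referred")
    stop("recording not flagged input-referred (units = ",
         if (is.null(meta$units)) "absent" else meta$units,
         "); remove the acquisition gain upstream")
  dt <- data.table::fread(path)
  need <- c("ch_contra", "ch_ipsi")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0)
    stop("missing channel(s): ", paste(miss, collapse = ", "),
         " (found: ", paste(names(dt), collapse = ", "), ")")
  onsets <- as.numeric(meta$stim_onsets)
  dur <- nrow(dt) / meta$sample_rate
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("stimulus onsets must be strictly increasing")
  if (length(onsets) > 0 && (min(onsets) < 0 || max(onsets) >= dur))
    stop("stimulus onsets outside the recording")
  rec <- list(
    ch_contra = dt$ch_contra,
    ch_ipsi = dt$ch_ipsi,
    sample_rate = meta$sample_rate,
    stim_onsets = onsets,
    protocol = make_protocol(meta$protocol$conc_pct,
                             meta$protocol$segment_minutes),
    animal_id = meta$animal_id,
    ground_truth = NULL
  )
  class(rec) <- "ecog_recording"
  rec
}

#' Write a table as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Write experiment outputs with a checksum manifest
#'
#' Serializes the artifacts of a [run_doa_experiment()] result
#' (predictions.tsv, metrics.tsv, importances.tsv, summary.json), a
#' copy of the run configuration (config.yaml), and a manifest.tsv
#' listing every written file with its MD5 checksum. Deterministic
#' results reproduce identical checksums.
#'
#' @param result A `doa_result` (or `NULL` to write config and
#'   manifest only).
#' @param out_dir Output directory (created if needed).
#' @param config Optional list serialized as config.yaml.
#' @return Data.frame manifest (file, md5), invisibly written to
#'   `manifest.tsv`.
#' @export
write_outputs <- function(result, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (!is.null(config)) {
    p <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, p)
    written <- c(written, p)
  }
  if (!is.null(result)) {
    stopifnot(inherits(result, "doa_result"))
    preds <- do.call(rbind, lapply(result$folds, function(f) {
      data.frame(animal_id = f$animal, t_s = f$t_s, y = f$y,
                 y_hat = f$y_hat, y_hat_se = f$y_hat_se)
    }))
    metrics <- do.call(rbind, lapply(result$folds, function(f) {
      row <- data.frame(animal_id = f$animal, mae = f$mae, r2 = f$r2)
      if (!is.null(f$classification)) {
        row$accuracy <- f$classification$accuracy
        row$f1 <- f$classification$f1
        row$precision <- f$classification$precision
        row$recall <- f$classification$recall
      }
      row
    }))
    imp <- data.frame(animal_id = rownames(result$importance_matrix),
                      result$importance_matrix, check.names = FALSE)
    files <- list(predictions.tsv = preds, metrics.tsv = metrics,
                  importances.tsv = imp)
    for (nm in names(files)) {
      p <- file.path(out_dir, nm)
      write_tsv(files[[nm]], p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, "summary.json")
    summ <- lapply(result$summary, as.list)
    if (!is.null(result$time_control))
      summ$time_control <- result$time_control[c("rho", "p")]
    jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
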