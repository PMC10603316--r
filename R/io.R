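#' Read and write epoched EEG as CSV
#'
#' On-disk interchange layout for epoched multichannel EEG: one row per
#' epoch-channel pair, header `epoch_id, channel_id, label, s0 ... s{n-1}`
#' where `s*` are the sample values. All rows of an epoch must carry the
#' same label; labels must be binary; every row must have the same number of
#' samples. The sampling rate travels in a `# fs=<Hz>` comment on the first
#' line.
#'
#' @param epochs an [epoch_set()].
#' @param path CSV file path.
#' @return `read_epochs_csv` returns an `epoch_set`; `write_epochs_csv`
#'   returns `path` invisibly. Round-trips are lossless to float-formatting
#'   precision.
#' @export
write_epochs_csv <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- n_epochs(epochs); nc <- n_channels(epochs); ns <- n_samples(epochs)
  flat <- matrix(NA_real_, ne * nc, ns)
  for (e in seq_len(ne)) {
    flat[(e - 1L) * nc + seq_len(nc), ] <- epochs$data[e, , ]
  }
  dt <- data.table::data.table(
    epoch_id = rep(seq_len(ne), each = nc),
    channel_id = rep(epochs$channel_ids, times = ne),
    label = rep(epochs$labels, each = nc))
  dt <- cbind(dt, data.table::as.data.table(flat))
  data.table::setnames(dt, c("epoch_id", "channel_id", "label",
                             paste0("s", seq_len(ns) - 1L)))
  writeLines(sprintf("# fs=%.10g", epochs$fs), path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @param fs sampling rate override in Hz; by default read from the file's
#'   `# fs=` header comment.
#' @export
read_epochs_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(fs)) {
    if (!grepl("^# fs=", first)) {
      stop("missing `# fs=` header; pass `fs` explicitly", call. = FALSE)
    }
    fs <- as.numeric(sub("^# fs=", "", first))
  }
  dt <- data.table::fread(path, skip = "epoch_id")
  need <- c("epoch_id", "channel_id", "label")
  if (!all(need %in% names(dt))) {
    stop("malformed header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scols <- grep("^s[0-9]+$", names(dt), value = TRUE)
  if (length(scols) == 0L) stop("no sample columns found", call. = FALSE)
  bad <- which(!stats::complete.cases(dt[, scols, with = FALSE]))
  if (length(bad)) {
    stop("ragged/missing sample values at data row ", bad[1L], call. = FALSE)
  }
  labs <- unique(dt$label)
  if (!all(labs %in% c(0, 1))) {
    stop("labels must be binary 0/1; found value ",
         setdiff(labs, c(0, 1))[1L], " at data row ",
         which(!dt$label %in% c(0, 1))[1L], call. = FALSE)
  }
  epoch_ids <- unique(dt$epoch_id)
  chan_ids <- unique(dt$channel_id)
  ne <- length(epoch_ids); nc <- length(chan_ids); ns <- length(scols)
  if (nrow(dt) != ne * nc) {
    stop("expected ", ne * nc, " rows (epochs x channels), found ", nrow(dt),
         call. = FALSE)
  }
  mat <- as.matrix(dt[, scols, with = FALSE])
  data <- array(NA_real_, c(ne, nc, ns))
  labels <- integer(ne)
  for (e in seq_len(ne)) {
    rows <- which(dt$epoch_id == epoch_ids[e])
    rows <- rows[match(chan_ids, dt$channel_id[rows])]
    if (anyNA(rows)) {
      stop("epoch ", epoch_ids[e], " is missing channels", call. = FALSE)
    }
    lab <- unique(dt$label[rows])
    if (length(lab) != 1L) {
      stop("epoch ", epoch_ids[e], " has inconsistent labels", call. = FALSE)
    }
    labels[e] <- as.integer(lab)
    data[e, , ] <- mat[rows, ]
  }
  epoch_set(data, fs, labels, as.character(chan_ids))
}

#' Read and write a feature matrix as CSV
#'
#' Header row names each feature `<channel>_<kind>_<index>`, plus a leading
#' `label` column.
#'
#' @param features a [feature_matrix()].
#' @param path CSV file path.
#' @export
write_feature_matrix_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  within_idx <- stats::ave(seq_along(features$channel_map),
                           features$channel_map, FUN = seq_along)
  cols <- sprintf("%s_%s_%d",
                  features$channel_ids[features$channel_map],
                  features$kind, within_idx)
  dt <- data.table::data.table(label = features$labels)
  vals <- data.table::as.data.table(features$values)
  data.table::setnames(vals, cols)
  data.table::fwrite(cbind(dt, vals), path)
  invisible(path)
}

#' @rdname write_feature_matrix_csv
#' @param kind feature kind recorded in the returned object.
#' @export
read_feature_matrix_csv <- function(path, kind = "spectral") {
  dt <- data.table::fread(path)
  if (!"label" %in% names(dt)) stop("missing `label` column", call. = FALSE)
  cols <- setdiff(names(dt), "label")
  chan <- sub("_(spectral|temporal)_[0-9]+$", "", cols)
  chan_ids <- unique(chan)
  feature_matrix(as.matrix(dt[, cols, with = FALSE]), dt$label,
                 match(chan, chan_ids), kind = kind, channel_ids = chan_ids)
}
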