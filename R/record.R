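#' Multirate channel record
#'
#' The in-memory representation of a recording session: one tibble per
#' sampling rate. `eeg` holds `time_s`, `eeg1_uv`, `eeg2_uv` at 400 Hz;
#' `periph` holds `time_s`, `eda_us`, `skt_c`, `ppg_red`, `ppg_ir`,
#' `acc_x_g`, `acc_y_g`, `acc_z_g` at 100 Hz.
#'
#' @param eeg tibble of EEG samples.
#' @param periph tibble of peripheral samples.
#' @param fs_eeg,fs_periph sampling rates in Hz.
#' @param diagnostics optional list (e.g. frame-gap table from decoding).
#' @return An object of class `multirate_record`.
#' @export
multirate_record <- function(eeg, periph, fs_eeg = 400, fs_periph = 100,
                             diagnostics = NULL) {
  eeg <- as_tibble(eeg)
  periph <- as_tibble(periph)
  need_eeg <- c("time_s", "eeg1_uv", "eeg2_uv")
  need_per <- c("time_s", "eda_us", "skt_c", "ppg_red", "ppg_ir",
                "acc_x_g", "acc_y_g", "acc_z_g")
  if (!all(need_eeg %in% names(eeg))) stop_data("`eeg` must have columns %s",
                                                paste(need_eeg, collapse = ", "))
  if (!all(need_per %in% names(periph))) stop_data("`periph` must have columns %s",
                                                   paste(need_per, collapse = ", "))
  structure(
    list(eeg = eeg, periph = periph, fs_eeg = fs_eeg, fs_periph = fs_periph,
         diagnostics = diagnostics),
    class = "multirate_record"
  )
}

#' @export
print.multirate_record <- function(x, ...) {
  dur <- if (nrow(x$eeg)) nrow(x$eeg) / x$fs_eeg else 0
  cat(sprintf("<multirate_record> %.2f s: %d EEG samples/channel @ %g Hz, %d peripheral samples/channel @ %g Hz\n",
              dur, nrow(x$eeg), x$fs_eeg, nrow(x$periph), x$fs_periph))
  if (!is.null(x$diagnostics$gaps) && nrow(x$diagnostics$gaps)) {
    cat(sprintf("  %d frame-index gap(s) flagged\n", nrow(x$diagnostics$gaps)))
  }
  invisible(x)
}

#' Duration of a record in seconds
#' @param record a [multirate_record].
#' @return Seconds covered by the peripheral stream.
#' @export
record_duration <- function(record) {
  nrow(record$periph) / record$fs_periph
}

#' Write / read a multirate record as per-rate CSV files
#'
#' One CSV per sampling rate (`<prefix>_eeg.csv`, `<prefix>_periph.csv`),
#' first column time in seconds, remaining columns the channels.
#'
#' @param record a [multirate_record].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return `write_record_csv()` returns the file paths invisibly;
#'   `read_record_csv()` returns a [multirate_record].
#' @export
write_record_csv <- function(record, dir, prefix = "record") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_eeg.csv", "_periph.csv")))
  write.csv(record$eeg, paths[1L], row.names = FALSE)
  write.csv(record$periph, paths[2L], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(dir, prefix = "record") {
  paths <- file.path(dir, paste0(prefix, c("_eeg.csv", "_periph.csv")))
  if (!all(file.exists(paths))) stop_data("record CSVs not found under %s", dir)
  eeg <- as_tibble(read.csv(paths[1L]))
  periph <- as_tibble(read.csv(paths[2L]))
  fs_eeg <- if (nrow(eeg) > 1L) round(1 / median(diff(eeg$time_s))) else 400
  fs_per <- if (nrow(periph) > 1L) round(1 / median(diff(periph$time_s))) else 100
  multirate_record(eeg, periph, fs_eeg = fs_eeg, fs_periph = fs_per)
}

#' @export
autoplot.multirate_record <- function(object, ...) {
  eeg_long <- tidyr::pivot_longer(object$eeg, -"time_s",
                                  names_to = "channel", values_to = "value")
  per_long <- tidyr::pivot_longer(object$periph, -"time_s",
                                  names_to = "channel", values_to = "value")
  dat <- dplyr::bind_rows(eeg_long, per_long)
  dat$channel <- factor(dat$channel, levels = unique(dat$channel))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (s)", y = NULL)
}
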