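# Plain-text serialization: events and spikes as TSV, configs / ground truth
# / results as JSON, signal arrays as RDS (runtime artifacts). The
# environment provides no HDF5 bindings for R, so RDS stands in for the
# heavy arrays; everything tabular stays in open text formats.

#' Write / read an event table as TSV
#' @param events Event table.
#' @param path File path.
#' @return `read_events_tsv` returns the event table.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ev$condition <- factor(ev$condition, levels = c("target", "distractor"))
  ev
}

#' Write / read a spike train as TSV
#'
#' Columns: `cluster_id`, `time_ms`, `depth_pct`, `paired_macro`.
#' @param train An [spike_train()].
#' @param path File path.
#' @return `read_spikes_tsv` returns a list of [spike_train()]s (one per
#'   cluster id present).
#' @export
write_spikes_tsv <- function(train, path) {
  df <- data.frame(cluster_id = train$cluster_id, time_ms = train$spike_times,
                   depth_pct = train$depth_pct,
                   paired_macro = train$paired_macro)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @export
read_spikes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(split(df, df$cluster_id), function(d)
    spike_train(d$time_ms, cluster_id = d$cluster_id[1],
                depth_pct = d$depth_pct[1], paired_macro = d$paired_macro[1]))
}
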