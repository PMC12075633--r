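#' Write traces as tab-delimited text with a metadata sidecar
#'
#' One file per trace with columns `time_s`, `I_D`, `I_A`, `I_AA`,
#' `segment`, `bg_D`, `bg_A`, plus a `metadata.tsv` table with `trace_id`,
#' `condition`, `atp_uM`, `frame_time_s` and the file name.
#'
#' @param traces list of `fret_trace`.
#' @param dir output directory (created when missing).
#' @return invisibly, the metadata data frame.
#' @export
write_traces <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- attr(tr, "trace_id") %||% sprintf("trace_%04d", i)
    file <- paste0(id, ".tsv")
    utils::write.table(as.data.frame(tr), file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    data.frame(trace_id = id,
               condition = attr(tr, "condition") %||% NA_character_,
               atp_uM = attr(tr, "atp") %||% NA_real_,
               frame_time_s = attr(tr, "frame_time") %||% NA_real_,
               file = file, stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(meta)
}

#' Read traces written by [write_traces()]
#'
#' @param dir directory containing `metadata.tsv` and the trace files.
#' @return list of `fret_trace`.
#' @export
read_traces <- function(dir) {
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    d <- utils::read.table(file.path(dir, meta$file[i]), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
    attr(d, "trace_id") <- meta$trace_id[i]
    attr(d, "condition") <- meta$condition[i]
    attr(d, "atp") <- meta$atp_uM[i]
    attr(d, "frame_time") <- meta$frame_time_s[i]
    class(d) <- c("fret_trace", "data.frame")
    d
  })
}
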