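# rbind a list of one-row data frames, falling back to a supplied empty
# prototype when there are no rows
rbind_rows <- function(rows, empty) {
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
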