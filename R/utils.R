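# Internal helpers: classed conditions and residue identifiers.
#
# Every user-facing failure mode raises a classed condition so callers (and
# the CLI) can branch on what went wrong rather than matching message text.

bj_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("bj_", class), "bj_error"), ...)
}

bj_warn <- function(message, class = "warning") {
  warn(message, class = c(paste0("bj_", class), "bj_warning"))
}

# A residue identifier is (number, insertion code); rendered "52" or "52A".
format_res_id <- function(resno, ins) {
  paste0(resno, ifelse(is.na(ins) | ins == "", "", ins))
}

# Parse "52" / "52A" -> list(resno, ins). Returns NULL on malformed input so
# callers can report the offending row/line themselves.
parse_res_id <- function(id) {
  id <- trimws(id)
  m <- regmatches(id, regexec("^(-?[0-9]+)([A-Za-z]?)$", id))[[1]]
  if (length(m) == 0) {
    return(NULL)
  }
  list(resno = as.integer(m[2]), ins = m[3])
}

# Locate residues (resno, ins) in a trace; NA where absent.
match_residue <- function(trace, resno, ins) {
  ins <- ifelse(is.na(ins), "", ins)
  match(paste(resno, ins), paste(trace$resno, trace$ins))
}
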