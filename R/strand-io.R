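# Readers for strand-boundary annotations. All return the same "raw strand"
# tibble so downstream validation (build_annotation) is source-agnostic:
#   chain, start_resno, start_ins, end_resno, end_ins, sheet_id, source

new_strand_table <- function(chain = character(), start_resno = integer(),
                             start_ins = character(), end_resno = integer(),
                             end_ins = character(), sheet_id = NA_character_,
                             source = character()) {
  tibble(
    chain = as.character(chain),
    start_resno = as.integer(start_resno), start_ins = as.character(start_ins),
    end_resno = as.integer(end_resno), end_ins = as.character(end_ins),
    sheet_id = as.character(sheet_id), source = as.character(source)
  )
}

#' Read strand ranges from PDB SHEET records
#'
#' One row per SHEET record on the chosen chain, in record order, with the
#' sheet identifier preserved. SHEET records routinely split a strand at a
#' beta-bulge; [build_annotation()] re-merges such fragments (default
#' `merge_gap = 1` for this source).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier.
#' @return A raw-strand tibble (`source = "sheet_record"`). An empty tibble
#'   plus a warning when the file has no SHEET records for the chain.
#' @export
read_sheet_strands <- function(path, chain) {
  if (!file.exists(path)) {
    bj_abort(paste0("PDB file not found: ", path), "missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  rec <- which(startsWith(lines, "SHEET"))
  out <- list()
  for (i in rec) {
    ln <- lines[i]
    init_chain <- substr(ln, 22, 22)
    if (init_chain != chain) next
    start <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    end <- suppressWarnings(as.integer(trimws(substr(ln, 34, 37))))
    if (is.na(start) || is.na(end)) {
      bj_abort(paste0("unparseable SHEET record at line ", i, " of ", path),
               "parse")
    }
    out[[length(out) + 1]] <- new_strand_table(
      chain = chain, start_resno = start,
      start_ins = trimws(substr(ln, 27, 27)),
      end_resno = end, end_ins = trimws(substr(ln, 38, 38)),
      sheet_id = trimws(substr(ln, 12, 14)), source = "sheet_record"
    )
  }
  if (length(out) == 0) {
    bj_warn(paste0("no SHEET records for chain ", chain, " in ", path),
            "no_sheet_records")
    return(new_strand_table())
  }
  bind_rows(out)
}

#' Read strand ranges from STRIDE output
#'
#' Contiguous runs of residues assigned the extended-strand state (one-letter
#' code `E`) on the chosen chain become strands, in chain (line) order. Only
#' `ASG` records are consulted.
#'
#' @param path Path to a STRIDE plain-text output file.
#' @param chain Chain identifier.
#' @return A raw-strand tibble (`source = "stride"`); empty when the chain
#'   has no `E` residues.
#' @export
read_stride_strands <- function(path, chain) {
  if (!file.exists(path)) {
    bj_abort(paste0("STRIDE file not found: ", path), "missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  asg <- which(startsWith(lines, "ASG"))
  resno <- integer(0); ins <- character(0); ss <- character(0)
  for (i in asg) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 6) {
      bj_abort(paste0("unparseable STRIDE ASG record at line ", i, " of ",
                      path), "parse")
    }
    if (tok[3] != chain) next
    id <- parse_res_id(tok[4])
    if (is.null(id)) {
      bj_abort(paste0("unparseable residue number '", tok[4], "' at line ",
                      i, " of ", path), "parse")
    }
    resno <- c(resno, id$resno); ins <- c(ins, id$ins)
    ss <- c(ss, tok[6])
  }
  if (length(ss) == 0 || !any(ss == "E")) {
    return(new_strand_table())
  }
  r <- rle(ss == "E")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  bind_rows(lapply(keep, function(k) {
    new_strand_table(
      chain = chain,
      start_resno = resno[starts[k]], start_ins = ins[starts[k]],
      end_resno = resno[ends[k]], end_ins = ins[ends[k]],
      source = "stride"
    )
  }))
}

#' Read strand ranges from a plain segment table
#'
#' Expects tab-separated text with a header line `chain<TAB>start<TAB>end`;
#' residue identifiers are `number[insertion_code]`, e.g. `52` or `52A`.
#'
#' @param path Path to the TSV file.
#' @return A raw-strand tibble (`source = "user_table"`).
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) {
    bj_abort(paste0("segment table not found: ", path), "missing_file")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("chain", "start", "end") %in% names(tab))) {
    bj_abort("segment table must have columns: chain, start, end", "parse")
  }
  if (nrow(tab) == 0) {
    return(new_strand_table())
  }
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    s <- parse_res_id(tab$start[r]); e <- parse_res_id(tab$end[r])
    if (is.null(s) || is.null(e) || is.na(tab$chain[r])) {
      bj_abort(paste0("malformed segment table row ", r), "parse")
    }
    if (e$resno < s$resno) {
      bj_abort(paste0("segment table row ", r, ": end residue precedes start"),
               "invalid_range")
    }
    new_strand_table(
      chain = tab$chain[r], start_resno = s$resno, start_ins = s$ins,
      end_resno = e$resno, end_ins = e$ins, source = "user_table"
    )
  })
  bind_rows(rows)
}

#' Read membrane-embedded segment ranges
#'
#' Reads a TSV with header `start<TAB>end`, one row per membrane-spanning
#' segment (the boundary style exported by membrane-topology databases).
#' The result feeds [apply_tm_boundaries()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with `start_resno`, `start_ins`, `end_resno`, `end_ins`.
#' @export
read_tm_table <- function(path) {
  if (!file.exists(path)) {
    bj_abort(paste0("TM table not found: ", path), "missing_file")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("start", "end") %in% names(tab))) {
    bj_abort("TM table must have columns: start, end", "parse")
  }
  if (nrow(tab) == 0) {
    return(tibble(start_resno = integer(), start_ins = character(),
                  end_resno = integer(), end_ins = character()))
  }
  bind_rows(lapply(seq_len(nrow(tab)), function(r) {
    s <- parse_res_id(tab$start[r]); e <- parse_res_id(tab$end[r])
    if (is.null(s) || is.null(e)) {
      bj_abort(paste0("malformed TM table row ", r), "parse")
    }
    tibble(start_resno = s$resno, start_ins = s$ins,
           end_resno = e$resno, end_ins = e$ins)
  }))
}
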