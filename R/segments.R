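# Validated strand/loop alternation. An annotation is a tibble with one row
# per segment, strands S_1..S_n interleaved with loops L_1..L_{n-1}:
#   kind ("strand"/"loop"), index, start_pos, end_pos (positions into the
#   trace; NA for a zero-residue loop), n_residues, start_id, end_id.
# Strand order is chain (sequence) order: the joints follow the chain, so
# spatial adjacency plays no role in the ordering.

new_segment_annotation <- function(segments, chain, n_strands) {
  out <- as_tibble(segments)
  attr(out, "chain") <- chain
  attr(out, "n_strands") <- as.integer(n_strands)
  class(out) <- c("segment_annotation", class(out))
  out
}

#' Number of strands in a segment annotation
#' @param annotation A `segment_annotation`.
#' @return Integer strand count n.
#' @export
n_strands <- function(annotation) {
  attr(annotation, "n_strands")
}

#' @export
print.segment_annotation <- function(x, ...) {
  cat("<segment_annotation> ", n_strands(x), " strands, chain ",
      attr(x, "chain"), "\n", sep = "")
  NextMethod()
}

#' Build a validated strand/loop annotation
#'
#' Turns raw strand ranges (from SHEET records, STRIDE output or a user
#' table) into the ordered alternation S_1, L_1, S_2, ..., L_{n-1}, S_n.
#' Strands are sorted into chain order, fragments separated by at most
#' `merge_gap` residues are merged (for SHEET input only fragments sharing a
#' sheet identifier merge, since beta-bulges split SHEET strands), and loops
#' are derived as the residue ranges between consecutive strands. Loops may
#' be empty: adjacent strands with no intervening residue are legal because
#' only the strand termini carry joints.
#'
#' @param strands Raw-strand tibble from [read_sheet_strands()],
#'   [read_stride_strands()] or [read_segment_table()].
#' @param trace A `calpha_trace` from [read_calpha_trace()].
#' @param merge_gap Maximum number of intervening residues across which two
#'   strand fragments are merged. `NULL` (default) picks 1 when every strand
#'   comes from SHEET records and 0 otherwise.
#' @param trim If `TRUE`, a strand terminus whose residue is absent from the
#'   trace (unresolved in the model) is moved inward to the nearest resolved
#'   residue, with a warning. The default is a hard error: joint positions
#'   define every downstream angle, so silent shifts are not acceptable.
#'
#' @return A `segment_annotation` with n >= 2 strands.
#' @export
build_annotation <- function(strands, trace, merge_gap = NULL, trim = FALSE) {
  if (nrow(strands) == 0) {
    bj_abort("no strands supplied (need at least 2)", "too_few_strands")
  }
  tr_chain <- trace$chain[1]
  st <- filter(strands, .data$chain == tr_chain)
  if (nrow(st) == 0) {
    bj_abort(paste0("no strands on trace chain '", tr_chain, "'"),
             "too_few_strands")
  }
  if (is.null(merge_gap)) {
    merge_gap <- if (all(st$source == "sheet_record")) 1L else 0L
  }
  if (merge_gap < 0) {
    bj_abort("merge_gap must be non-negative", "bad_config")
  }

  locate <- function(resno, ins, other_resno, which) {
    pos <- match_residue(trace, resno, ins)
    if (!is.na(pos)) {
      return(pos)
    }
    if (!trim) {
      bj_abort(paste0("strand terminus ", format_res_id(resno, ins),
                      " has no C-alpha in the trace (use trim = TRUE to ",
                      "shrink to the nearest resolved residue)"),
               "missing_terminus")
    }
    lo <- min(resno, other_resno); hi <- max(resno, other_resno)
    inside <- which(trace$resno >= lo & trace$resno <= hi)
    if (length(inside) == 0) {
      bj_abort(paste0("no resolved residue inside strand ",
                      format_res_id(resno, ins), "-", other_resno),
               "missing_terminus")
    }
    pos <- if (which == "start") min(inside) else max(inside)
    bj_warn(paste0("strand terminus ", format_res_id(resno, ins),
                   " unresolved; trimmed to ",
                   format_res_id(trace$resno[pos], trace$ins[pos])),
            "trimmed_terminus")
    pos
  }

  st$start_pos <- vapply(seq_len(nrow(st)), function(i) {
    locate(st$start_resno[i], st$start_ins[i], st$end_resno[i], "start")
  }, integer(1))
  st$end_pos <- vapply(seq_len(nrow(st)), function(i) {
    locate(st$end_resno[i], st$end_ins[i], st$start_resno[i], "end")
  }, integer(1))

  if (any(st$start_pos > st$end_pos)) {
    bj_abort("strand with end residue before start residue in chain order",
             "bad_annotation")
  }
  st <- arrange(st, .data$start_pos)

  # merge fragments, then detect overlap
  merged <- st[1, , drop = FALSE]
  for (i in seq_len(nrow(st))[-1]) {
    cur <- merged[nrow(merged), ]
    gap <- st$start_pos[i] - cur$end_pos - 1L
    same_sheet <- !identical(cur$source, "sheet_record") ||
      identical(cur$sheet_id, st$sheet_id[i])
    if (gap < 0) {
      bj_abort("overlapping strand ranges in annotation", "bad_annotation")
    } else if (merge_gap > 0 && gap <= merge_gap && same_sheet) {
      # merge_gap = 0 disables merging entirely, so deliberately adjacent
      # strands keep their zero-residue loop instead of collapsing
      merged$end_pos[nrow(merged)] <- st$end_pos[i]
      merged$end_resno[nrow(merged)] <- st$end_resno[i]
      merged$end_ins[nrow(merged)] <- st$end_ins[i]
    } else {
      merged <- bind_rows(merged, st[i, ])
    }
  }

  n <- nrow(merged)
  if (n < 2) {
    bj_abort(paste0("annotation has ", n, " strand(s) after merging; ",
                    "at least 2 are required"), "too_few_strands")
  }
  assemble_annotation(merged$start_pos, merged$end_pos, trace)
}

# Build the strand/loop alternation from strand position ranges.
assemble_annotation <- function(start_pos, end_pos, trace) {
  n <- length(start_pos)
  id_at <- function(p) format_res_id(trace$resno[p], trace$ins[p])
  seg <- list()
  for (i in seq_len(n)) {
    sp <- start_pos[i]; ep <- end_pos[i]
    seg[[length(seg) + 1]] <- tibble(
      kind = "strand", index = i,
      start_pos = sp, end_pos = ep,
      n_residues = ep - sp + 1L,
      start_id = id_at(sp), end_id = id_at(ep)
    )
    if (i < n) {
      ls <- end_pos[i] + 1L; le <- start_pos[i + 1] - 1L
      empty <- ls > le
      seg[[length(seg) + 1]] <- tibble(
        kind = "loop", index = i,
        start_pos = if (empty) NA_integer_ else ls,
        end_pos = if (empty) NA_integer_ else le,
        n_residues = if (empty) 0L else le - ls + 1L,
        start_id = if (empty) NA_character_ else id_at(ls),
        end_id = if (empty) NA_character_ else id_at(le)
      )
    }
  }
  new_segment_annotation(bind_rows(seg), trace$chain[1], n)
}

#' Extract the strand ranges of an annotation as a raw-strand table
#'
#' The inverse of [build_annotation()] up to merging: feeding the result
#' back through `build_annotation(..., merge_gap = 0)` reproduces the
#' annotation exactly.
#'
#' @param annotation A `segment_annotation`.
#' @param trace The `calpha_trace` the annotation was built on.
#' @return A raw-strand tibble (`source = "user_table"`).
#' @export
annotation_strands <- function(annotation, trace) {
  s <- filter(annotation, .data$kind == "strand")
  new_strand_table(
    chain = attr(annotation, "chain"),
    start_resno = trace$resno[s$start_pos], start_ins = trace$ins[s$start_pos],
    end_resno = trace$resno[s$end_pos], end_ins = trace$ins[s$end_pos],
    source = "user_table"
  )
}

#' Override strand boundaries with membrane-embedded segment ranges
#'
#' Replaces each strand's range by its intersection with the matching
#' membrane-spanning range, so that joints sit on the membrane boundary
#' rather than the full secondary-structure strand. Each TM range must
#' intersect exactly one strand; strand count is unchanged and loops are
#' re-derived.
#'
#' @param annotation A `segment_annotation`.
#' @param tm_ranges Tibble from [read_tm_table()] (columns `start_resno`,
#'   `start_ins`, `end_resno`, `end_ins`), or a two-column data frame of
#'   numeric `start`/`end` residue numbers.
#' @param trace The `calpha_trace` the annotation was built on.
#' @return A new `segment_annotation` with the same number of strands.
#' @export
apply_tm_boundaries <- function(annotation, tm_ranges, trace) {
  tm <- as_tibble(tm_ranges)
  if (all(c("start", "end") %in% names(tm)) && !"start_resno" %in% names(tm)) {
    tm <- tibble(start_resno = as.integer(tm$start), start_ins = "",
                 end_resno = as.integer(tm$end), end_ins = "")
  }
  s <- filter(annotation, .data$kind == "strand")
  start_pos <- s$start_pos
  end_pos <- s$end_pos
  s_start_resno <- trace$resno[start_pos]
  s_end_resno <- trace$resno[end_pos]

  for (r in seq_len(nrow(tm))) {
    lo <- tm$start_resno[r]; hi <- tm$end_resno[r]
    hits <- which(s_start_resno <= hi & s_end_resno >= lo)
    if (length(hits) != 1) {
      bj_abort(paste0("TM range ", lo, "-", hi, " intersects ",
                      length(hits), " strands (must be exactly 1)"),
               "ambiguous_boundary")
    }
    i <- hits
    in_range <- which(trace$resno >= max(lo, s_start_resno[i]) &
                        trace$resno <= min(hi, s_end_resno[i]))
    in_range <- in_range[in_range >= start_pos[i] & in_range <= end_pos[i]]
    if (length(in_range) == 0) {
      bj_abort(paste0("TM range ", lo, "-", hi,
                      " leaves strand ", i, " without resolved residues"),
               "missing_terminus")
    }
    start_pos[i] <- min(in_range)
    end_pos[i] <- max(in_range)
    s_start_resno[i] <- trace$resno[start_pos[i]]
    s_end_resno[i] <- trace$resno[end_pos[i]]
  }
  assemble_annotation(start_pos, end_pos, trace)
}
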