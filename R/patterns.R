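# Sign, dyad/triad, quadrant and histogram statistics over descriptor
# angles. All sliding windows are taken within one structure and one angle
# type; group-level aggregation sums counts and never concatenates sign
# strings across structures.

SIGNS <- c("+", "-")
QUADRANTS <- c("+A", "-A", "+B", "-B")

check_angle_domain <- function(angle) {
  if (any(!is.finite(angle)) || any(angle <= -180 | angle > 180)) {
    bj_abort("angles must lie in (-180, 180]", "domain")
  }
}

#' Sign of a dihedral angle
#'
#' Positive angles (0 to +180 degrees, zero inclusive) are clockwise and
#' map to `"+"`; negative angles to `"-"`.
#'
#' @param angle Numeric vector of angles in (-180, 180].
#' @return Character vector over `{"+", "-"}`.
#' @export
sign_of <- function(angle) {
  check_angle_domain(angle)
  ifelse(angle >= 0, "+", "-")
}

#' Quadrant label of a dihedral angle
#'
#' Splits the angle domain into four 90-degree sectors:
#' `+A` = \[0, 90), `+B` = \[90, 180\], `-A` = \[-90, 0), `-B` = (-180, -90).
#' Boundaries are pinned left-closed (and +180 closed at the top) so that
#' every angle belongs to exactly one sector.
#'
#' @param angle Numeric vector of angles in (-180, 180].
#' @return Character vector over `{"+A", "+B", "-A", "-B"}`.
#' @export
quadrant_of <- function(angle) {
  check_angle_domain(angle)
  ifelse(angle >= 90, "+B",
         ifelse(angle >= 0, "+A",
                ifelse(angle >= -90, "-A", "-B")))
}

as_sign_vector <- function(signs) {
  if (length(signs) == 1 && !signs %in% SIGNS && nchar(signs) != 1) {
    signs <- strsplit(signs, "")[[1]]
  }
  if (length(signs) > 0 && !all(signs %in% SIGNS)) {
    bj_abort("signs must be '+' or '-'", "domain")
  }
  signs
}

window_counts <- function(labels, levels, width) {
  grid <- do.call(expand.grid, c(rep(list(levels), width),
                                 list(stringsAsFactors = FALSE)))
  names(grid) <- paste0("pos", seq_len(width))
  # enumerate in odometer order with the first position varying slowest
  grid <- grid[do.call(order, lapply(grid, function(col) match(col, levels))), ]
  key <- apply(grid, 1, paste, collapse = ",")
  counts <- setNames(integer(length(key)), key)
  L <- length(labels)
  if (L >= width) {
    for (s in seq_len(L - width + 1)) {
      k <- paste(labels[s:(s + width - 1)], collapse = ",")
      counts[k] <- counts[k] + 1L
    }
  }
  out <- as_tibble(grid)
  out$pattern <- paste0("(", key, ")")
  out$n <- as.integer(counts)
  rownames(out) <- NULL
  out
}

#' Dyad (consecutive-pair) sign pattern counts
#'
#' Sliding window of width 2, step 1, over the ordered sign string of one
#' structure and one angle type: consecutive indices only, so angle i is
#' paired with angle i+1 and never with i+2.
#'
#' @param signs Character vector over `{"+", "-"}` (or a single string like
#'   `"++-"`), the ordered signs of one structure's beta or gamma angles.
#' @return A four-row tibble with `pos1`, `pos2`, `pattern` and count `n`,
#'   in the fixed order (+,+), (+,-), (-,+), (-,-). All-zero counts when
#'   fewer than two signs are supplied.
#' @examples
#' dyad_counts(c("+", "-", "+"))
#' @export
dyad_counts <- function(signs) {
  window_counts(as_sign_vector(signs), SIGNS, 2L)
}

#' Triad (consecutive-triple) sign pattern counts
#'
#' Sliding window of width 3 over the ordered sign string; counts over the
#' eight ordered sign triples.
#'
#' @inheritParams dyad_counts
#' @return An eight-row tibble with `pos1`..`pos3`, `pattern`, `n`.
#' @export
triad_counts <- function(signs) {
  window_counts(as_sign_vector(signs), SIGNS, 3L)
}

#' Quadrant dyad counts for consecutive gamma angles
#'
#' Maps each gamma angle to its quadrant ([quadrant_of()]) and counts the
#' 16 ordered quadrant pairs over a sliding window of width 2.
#'
#' @param gamma_angles Ordered numeric vector: the consecutive gamma-type
#'   angles of one structure.
#' @return A 16-row tibble with `pos1`, `pos2`, `pattern`, `n`.
#' @export
quadrant_dyad_counts <- function(gamma_angles) {
  labels <- if (length(gamma_angles)) quadrant_of(gamma_angles) else character()
  window_counts(labels, QUADRANTS, 2L)
}

#' Histogram of dihedral angles
#'
#' Left-closed, right-open bins over \[-180, 180), with +180 counted in the
#' top bin. The bin width must divide 360.
#'
#' @param angles Numeric vector of angles in (-180, 180].
#' @param bin_width Bin width in degrees (default 10, the finest granularity
#'   at which sub-ranges of the distributions are usually discussed).
#' @return A tibble with `bin_start`, `bin_end` (degrees) and count `n`.
#' @export
angle_histogram <- function(angles, bin_width = 10) {
  if (length(bin_width) != 1 || bin_width <= 0 || 360 %% bin_width != 0) {
    bj_abort("bin_width must be a positive divisor of 360", "bad_config")
  }
  if (length(angles)) check_angle_domain(angles)
  n_bins <- as.integer(360 / bin_width)
  starts <- -180 + bin_width * (seq_len(n_bins) - 1)
  idx <- pmin(floor((angles + 180) / bin_width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(bin_start = starts, bin_end = starts + bin_width,
         n = as.integer(counts))
}

#' Pattern summary of one or more descriptors
#'
#' Computes sign strings, dyad/triad counts for beta and gamma angles,
#' quadrant dyad counts for gamma angles, and per-type histograms. Windows
#' are taken within each structure; counts are then summed, so dyads and
#' triads never cross structure boundaries.
#'
#' @param descriptors A `barrel_descriptor`, or several bound together with
#'   [dplyr::bind_rows()] (distinguished by `structure_id`).
#' @param bin_width Histogram bin width in degrees.
#' @return A list of class `pattern_summary` with elements `signs`,
#'   `dyads`, `triads`, `gamma_quadrant_dyads`, `histograms` and
#'   `n_structures`.
#' @export
pattern_summary <- function(descriptors, bin_width = 10) {
  d <- as_tibble(descriptors)
  d$structure_id <- ifelse(is.na(d$structure_id), "<unnamed>", d$structure_id)
  d <- arrange(d, .data$structure_id, .data$index)

  per_structure <- function(fn, type) {
    sub <- d[d$type == type, ]
    if (nrow(sub) == 0) {
      return(fn(numeric(0)))  # e.g. no gamma angles when every n = 2
    }
    tabs <- lapply(split(sub, sub$structure_id),
                   function(s) fn(s$angle[order(s$type_index)]))
    sum_pattern_tables(tabs)
  }
  sign_fn <- function(a) sign_of(a)

  signs <- d |>
    group_by(.data$structure_id, .data$type) |>
    summarise(signs = paste(sign_of(.data$angle[order(.data$type_index)]),
                            collapse = ""),
              .groups = "drop")

  out <- list(
    signs = signs,
    dyads = bind_rows(
      mutate(per_structure(function(a) dyad_counts(sign_fn(a)), "beta"),
             type = "beta", .before = 1),
      mutate(per_structure(function(a) dyad_counts(sign_fn(a)), "gamma"),
             type = "gamma", .before = 1)
    ),
    triads = bind_rows(
      mutate(per_structure(function(a) triad_counts(sign_fn(a)), "beta"),
             type = "beta", .before = 1),
      mutate(per_structure(function(a) triad_counts(sign_fn(a)), "gamma"),
             type = "gamma", .before = 1)
    ),
    gamma_quadrant_dyads = per_structure(quadrant_dyad_counts, "gamma"),
    histograms = bind_rows(
      mutate(angle_histogram(d$angle[d$type == "beta"], bin_width),
             type = "beta", .before = 1),
      mutate(angle_histogram(d$angle[d$type == "gamma"], bin_width),
             type = "gamma", .before = 1)
    ),
    n_structures = length(unique(d$structure_id))
  )
  class(out) <- "pattern_summary"
  out
}

sum_pattern_tables <- function(tabs) {
  if (length(tabs) == 0) {
    bj_abort("no structures to summarise", "domain")
  }
  out <- tabs[[1]]
  if (length(tabs) > 1) {
    out$n <- as.integer(Reduce(`+`, lapply(tabs, function(t) t$n)))
  }
  out
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("<pattern_summary> ", x$n_structures, " structure(s)\n", sep = "")
  cat("dyads:\n")
  print(as.data.frame(x$dyads[x$dyads$n > 0, c("type", "pattern", "n")]),
        row.names = FALSE)
  invisible(x)
}

#' Define a strand-count grouping scheme
#'
#' @param name Scheme name.
#' @param bins Named list of integer vectors of strand counts; bins must be
#'   disjoint so that every structure maps to at most one bin.
#' @return A `grouping_scheme` object.
#' @export
grouping_scheme <- function(name, bins) {
  if (is.null(names(bins)) || any(names(bins) == "")) {
    bj_abort("bins must be a named list", "bad_config")
  }
  all_n <- unlist(bins)
  if (anyDuplicated(all_n)) {
    bj_abort("grouping bins must be disjoint", "bad_config")
  }
  structure(list(name = name, bins = lapply(bins, as.integer)),
            class = "grouping_scheme")
}

#' Default grouping for transmembrane barrels
#'
#' Small (4-10), medium (12-16) and large (18-26) strand-count groups.
#' @return A `grouping_scheme`.
#' @export
tm_scheme <- function() {
  grouping_scheme("tm", list(`4-10` = 4:10, `12-16` = 12:16, `18-26` = 18:26))
}

#' Default grouping for cytoplasmic barrels
#'
#' 4-6, 7-8 and 10-14 strand-count groups.
#' @return A `grouping_scheme`.
#' @export
cyto_scheme <- function() {
  grouping_scheme("cyto", list(`4-6` = 4:6, `7-8` = 7:8, `10-14` = 10:14))
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat("<grouping_scheme> ", x$name, ": ",
      paste(names(x$bins), collapse = ", "), "\n", sep = "")
  invisible(x)
}

scheme_group_of <- function(scheme, n_strands) {
  labels <- rep(NA_character_, length(n_strands))
  for (lbl in names(scheme$bins)) {
    labels[n_strands %in% scheme$bins[[lbl]]] <- lbl
  }
  labels
}

#' Aggregate descriptors of many structures by strand-count group
#'
#' Assigns each structure to a bin of the grouping scheme by its strand
#' count, computes a [pattern_summary()] per group (summing counts, never
#' concatenating sign strings across structures), and returns a
#' per-position angle table for scatter-style plots. Structures whose
#' strand count falls in no bin are excluded with a warning.
#'
#' @param descriptors Bound `barrel_descriptor` rows of several structures;
#'   each structure needs a distinct `structure_id`.
#' @param scheme A `grouping_scheme`, e.g. [tm_scheme()] or [cyto_scheme()].
#' @param bin_width Histogram bin width in degrees.
#' @return A list of class `grouped_patterns`: `group_dyads`,
#'   `group_triads`, `group_quadrant_dyads`, `group_histograms` (tibbles
#'   with a `group` column), `positions` (structure_id, group, n_strands,
#'   type, type_index, angle) and `scheme`.
#' @export
aggregate_patterns <- function(descriptors, scheme, bin_width = 10) {
  d <- as_tibble(descriptors)
  d$group <- scheme_group_of(scheme, d$n_strands)
  dropped <- unique(d$structure_id[is.na(d$group)])
  if (length(dropped) > 0) {
    bj_warn(paste0(length(dropped), " structure(s) outside all bins of ",
                   "scheme '", scheme$name, "' excluded: ",
                   paste(dropped, collapse = ", ")),
            "outside_scheme")
    d <- filter(d, !is.na(.data$group))
  }
  if (nrow(d) == 0) {
    bj_abort("no structures fall inside the grouping scheme", "domain")
  }
  groups <- split(d, d$group)
  per_group <- function(elem) {
    bind_rows(lapply(names(groups), function(g) {
      ps <- pattern_summary(groups[[g]], bin_width = bin_width)
      mutate(ps[[elem]], group = g, .before = 1)
    }))
  }
  out <- list(
    group_dyads = per_group("dyads"),
    group_triads = per_group("triads"),
    group_quadrant_dyads = per_group("gamma_quadrant_dyads"),
    group_histograms = per_group("histograms"),
    positions = select(d, "structure_id", "group", "n_strands", "type",
                       "type_index", "angle"),
    scheme = scheme
  )
  class(out) <- "grouped_patterns"
  out
}

#' @export
print.grouped_patterns <- function(x, ...) {
  cat("<grouped_patterns> scheme '", x$scheme$name, "', groups: ",
      paste(unique(x$group_dyads$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}
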