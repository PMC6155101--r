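# Idealized barrel and flat-sheet generators. These exist so that every
# descriptor property (limiting cases, handedness, mirror behaviour,
# counting laws) is testable from first principles without external
# structures. Loops are minimal straight-line interpolations: the joints
# are strand termini only, so loop geometry never enters the descriptor
# and no realism is attempted there.

#' Specify an idealized beta-barrel
#'
#' Strands sit on a cylinder, one per azimuthal step of 360/n degrees.
#' `twist` is the azimuthal shear of each strand: the advance (in degrees)
#' of a strand's top end relative to its bottom end, the idealized
#' counterpart of the strand tilt a barrel's shear number sets. Its sign is
#' the handedness: positive twist builds the naturally occurring
#' right-handed barrel (every descriptor angle positive at the default
#' geometry), negative twist its mirror image. A small per-strand axial
#' stagger (an open-spiral rim) keeps the geometry away from the degenerate
#' aligned configurations that arise when the shear equals the azimuthal
#' step exactly.
#'
#' @param n_strands Number of strands (>= 2).
#' @param radius Barrel radius in Angstrom; default places consecutive
#'   strands 4.6 Angstrom apart along the circumference.
#' @param strand_length Residues per strand (>= 2).
#' @param rise Axial rise per residue along a strand, Angstrom.
#' @param twist Azimuthal shear per strand in degrees (sign = handedness).
#' @param direction `"antiparallel"` (alternating up/down), `"parallel"`
#'   (all up), or a logical vector of length `n_strands` (`TRUE` = up) for
#'   mixed topologies.
#' @param loop_residues Residues interpolated between consecutive strands.
#' @param stagger Axial offset between consecutive strands, Angstrom.
#' @param jitter Half-width of uniform coordinate noise, Angstrom (<= 0.05);
#'   0 disables.
#' @param seed Integer seed for the jitter; required when `jitter > 0`.
#' @return A `barrel_spec` object.
#' @export
barrel_spec <- function(n_strands, radius = NULL, strand_length = 10,
                        rise = 3.3, twist = 95,
                        direction = "antiparallel", loop_residues = 3,
                        stagger = 3, jitter = 0, seed = NULL) {
  n <- as.integer(n_strands)
  if (is.na(n) || n < 2) bj_abort("n_strands must be >= 2", "bad_spec")
  radius <- radius %||% (n * 4.6 / (2 * pi))
  if (radius <= 0) bj_abort("radius must be positive", "bad_spec")
  if (strand_length < 2) bj_abort("strand_length must be >= 2", "bad_spec")
  if (rise <= 0) bj_abort("rise must be positive", "bad_spec")
  if (loop_residues < 0) bj_abort("loop_residues must be >= 0", "bad_spec")
  up <- switch(
    as.character(direction[1]),
    antiparallel = rep(c(TRUE, FALSE), length.out = n),
    parallel = rep(TRUE, n),
    {
      if (!is.logical(direction) || length(direction) != n) {
        bj_abort("direction must be 'antiparallel', 'parallel' or a logical
                  vector of length n_strands", "bad_spec")
      }
      direction
    }
  )
  if (jitter < 0 || jitter > 0.05) {
    bj_abort("jitter must be in [0, 0.05] Angstrom", "bad_spec")
  }
  if (jitter > 0 && is.null(seed)) {
    bj_abort("jitter requires a seed", "bad_spec")
  }
  structure(
    list(n_strands = n, radius = radius,
         strand_length = as.integer(strand_length), rise = rise,
         twist = twist, up = up, loop_residues = as.integer(loop_residues),
         stagger = stagger, jitter = jitter, seed = seed),
    class = "barrel_spec"
  )
}

#' @export
print.barrel_spec <- function(x, ...) {
  cat("<barrel_spec> n=", x$n_strands, " R=", round(x$radius, 2),
      "A twist=", x$twist, " deg (",
      if (x$twist > 0) "right-handed" else if (x$twist < 0) "left-handed"
      else "untwisted", ")\n", sep = "")
  invisible(x)
}

#' Generate an idealized barrel trace and its annotation
#'
#' Builds the C-alpha trace residue by residue: strand k runs along the
#' cylinder at azimuth `k * 360/n`, sheared by `twist` degrees from bottom
#' to top, starting at axial offset `(k-1) * stagger`; "down" strands are
#' traversed top-to-bottom by the chain. Loops are straight-line
#' interpolations between consecutive strand termini. A negative twist
#' produces the exact mirror image (reflection through the xy-plane) of the
#' positive-twist barrel.
#'
#' @param spec A [barrel_spec()].
#' @return A list with elements `trace` (a `calpha_trace`) and `annotation`
#'   (a `segment_annotation`).
#' @examples
#' b <- generate_barrel(barrel_spec(8))
#' compute_descriptor(extract_joints(b$trace, b$annotation))
#' @export
generate_barrel <- function(spec) {
  if (!inherits(spec, "barrel_spec")) {
    bj_abort("spec must be a barrel_spec", "bad_spec")
  }
  n <- spec$n_strands; L <- spec$strand_length
  delta <- 2 * pi / n
  shear <- abs(spec$twist) * pi / 180
  height <- (L - 1) * spec$rise

  strand_xyz <- function(k) {
    # spatial parameter t in [0, 1] from bottom to top of strand k
    t <- (seq_len(L) - 1) / (L - 1)
    if (!spec$up[k]) t <- rev(t)
    az <- k * delta - shear * t
    cbind(spec$radius * cos(az), spec$radius * sin(az),
          (k - 1) * spec$stagger + t * height)
  }

  coords <- list(); start_pos <- integer(n); end_pos <- integer(n)
  pos <- 0L
  for (k in seq_len(n)) {
    s <- strand_xyz(k)
    start_pos[k] <- pos + 1L
    end_pos[k] <- pos + L
    coords[[length(coords) + 1]] <- s
    pos <- pos + L
    if (k < n && spec$loop_residues > 0) {
      a <- s[L, ]; b <- strand_xyz(k + 1)[1, ]
      f <- seq_len(spec$loop_residues) / (spec$loop_residues + 1)
      coords[[length(coords) + 1]] <-
        cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]),
              a[3] + f * (b[3] - a[3]))
      pos <- pos + spec$loop_residues
    }
  }
  xyz <- do.call(rbind, coords)
  if (spec$twist < 0) xyz[, 3] <- -xyz[, 3]
  if (spec$jitter > 0) {
    xyz <- withr::with_seed(spec$seed, {
      xyz + matrix(stats::runif(length(xyz), -spec$jitter, spec$jitter),
                   ncol = 3)
    })
  }
  trace <- new_calpha_trace(
    chain = "A", resno = seq_len(nrow(xyz)), ins = "", resname = "ALA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  list(trace = trace,
       annotation = assemble_annotation(start_pos, end_pos, trace))
}

#' Generate an idealized flat (coplanar) beta-sheet
#'
#' Limiting-case fixtures for the descriptor. Antiparallel sheets with the
#' default same-side placement have every beta and gamma angle exactly 0:
#' strand spatial positions zigzag relative to chain order, so strands i
#' and i+2 always sit on the same side of strand i+1. With
#' `same_side = FALSE` strands form a linear row in chain order, which puts
#' strand i+2 on the opposite side: gamma angles become exactly +/-180
#' (antiparallel) while beta stays 0. Parallel sheets have every beta angle
#' exactly +180 regardless of placement.
#'
#' @param n_strands Number of strands (>= 2).
#' @param parallel If `TRUE`, all strands run in the same direction.
#' @param spacing Distance between neighbouring strand axes, Angstrom.
#' @param strand_length Residues per strand.
#' @param rise Rise per residue along a strand, Angstrom.
#' @param loop_residues Residues interpolated between consecutive strands.
#' @param same_side Placement of successive strands (see Details).
#' @return A list with `trace` and `annotation`, as [generate_barrel()].
#' @export
generate_flat_sheet <- function(n_strands, parallel = FALSE, spacing = 4.8,
                                strand_length = 10, rise = 3.4,
                                loop_residues = 2, same_side = TRUE) {
  n <- as.integer(n_strands)
  if (is.na(n) || n < 2) bj_abort("n_strands must be >= 2", "bad_spec")
  if (strand_length < 2) bj_abort("strand_length must be >= 2", "bad_spec")
  L <- strand_length
  if (same_side) {
    # interleave: odd strands at 0,1,2,... even strands at m, m+1, ...
    m <- ceiling(n / 2)
    slot <- integer(n)
    slot[seq(1, n, 2)] <- seq_len(length(seq(1, n, 2))) - 1
    slot[seq(2, n, 2)] <- m + seq_len(length(seq(2, n, 2))) - 1
    xs <- slot * spacing
  } else {
    xs <- (seq_len(n) - 1) * spacing
  }
  up <- if (parallel) rep(TRUE, n) else rep(c(TRUE, FALSE), length.out = n)

  coords <- list(); start_pos <- integer(n); end_pos <- integer(n)
  pos <- 0L
  strand_xyz <- function(k) {
    y <- (seq_len(L) - 1) * rise
    if (!up[k]) y <- rev(y)
    cbind(rep(xs[k], L), y, rep(0, L))
  }
  for (k in seq_len(n)) {
    s <- strand_xyz(k)
    start_pos[k] <- pos + 1L; end_pos[k] <- pos + L
    coords[[length(coords) + 1]] <- s
    pos <- pos + L
    if (k < n && loop_residues > 0) {
      a <- s[L, ]; b <- strand_xyz(k + 1)[1, ]
      f <- seq_len(loop_residues) / (loop_residues + 1)
      coords[[length(coords) + 1]] <-
        cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]),
              rep(0, loop_residues))
      pos <- pos + loop_residues
    }
  }
  xyz <- do.call(rbind, coords)
  trace <- new_calpha_trace(
    chain = "A", resno = seq_len(nrow(xyz)), ins = "", resname = "ALA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  list(trace = trace,
       annotation = assemble_annotation(start_pos, end_pos, trace))
}

#' Reflect a trace through a coordinate plane
#'
#' Mirror-image fixture helper: reflection negates every torsion angle of
#' the descriptor (with +180 mapping to itself).
#'
#' @param trace A `calpha_trace`.
#' @param plane One of `"xy"`, `"xz"`, `"yz"`.
#' @return The reflected `calpha_trace`.
#' @export
reflect_trace <- function(trace, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  axis <- switch(plane, xy = "z", xz = "y", yz = "x")
  trace[[axis]] <- -trace[[axis]]
  trace
}

#' Write a C-alpha trace and its strand annotation as PDB
#'
#' Emits fixed-width ATOM records (C-alpha only) plus one SHEET record per
#' strand, so that [read_calpha_trace()] and [read_sheet_strands()] recover
#' the structure. Coordinates survive the round trip to within the 1e-3
#' Angstrom precision of the fixed-width format.
#'
#' @param trace A `calpha_trace`.
#' @param annotation A `segment_annotation` for the same trace.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(trace, annotation, path) {
  s <- filter(annotation, .data$kind == "strand")
  n <- nrow(s)
  sheet <- vapply(seq_len(n), function(i) {
    sp <- s$start_pos[i]; ep <- s$end_pos[i]
    sprintf("SHEET  %3d %3s%2d %3s %1s%4d%1s %3s %1s%4d%1s%2d",
            i, "A", n,
            trace$resname[sp], trace$chain[sp], trace$resno[sp],
            substr(paste0(trace$ins[sp], " "), 1, 1),
            trace$resname[ep], trace$chain[ep], trace$resno[ep],
            substr(paste0(trace$ins[ep], " "), 1, 1),
            if (i == 1) 0L else -1L)
  }, character(1))
  atoms <- vapply(seq_len(nrow(trace)), function(i) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, trace$resname[i], trace$chain[i], trace$resno[i],
            substr(paste0(trace$ins[i], " "), 1, 1),
            trace$x[i], trace$y[i], trace$z[i], 1, 0)
  }, character(1))
  ok <- tryCatch({
    writeLines(c(sheet, atoms, "END"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) {
    bj_abort(paste0("cannot write PDB file: ", path), "unwritable")
  }
  invisible(path)
}

#' Write an annotation's strand ranges as a segment table
#'
#' The TSV counterpart of [write_pdb()]; readable by [read_segment_table()].
#'
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(trace, annotation, path) {
  st <- annotation_strands(annotation, trace)
  readr::write_tsv(
    tibble(chain = st$chain,
           start = format_res_id(st$start_resno, st$start_ins),
           end = format_res_id(st$end_resno, st$end_ins)),
    path, progress = FALSE
  )
  invisible(path)
}
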