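# The joint-based descriptor: strand termini -> joint points -> alternating
# beta/gamma signed torsion series.
#
# For n strands there are 2n joints P_1..P_2n (first and last C-alpha of
# each strand, in chain order) and 2n-3 angles: the torsion over each
# sliding window of four consecutive joints. Odd windows span
# Strand-Loop-Strand and are beta-type (adjacent-strand arrangement:
# 0 = antiparallel, +/-180 = parallel); even windows span Loop-Strand-Loop
# and are gamma-type (relative placement of strands i and i+2 about i+1:
# 0 = same side, +/-180 = opposite sides).

#' Extract joint points from strand termini
#'
#' The C-alpha of the first and of the last residue of each strand become
#' joint points, in chain order: joint 2i-1 is the first residue of strand
#' S_i, joint 2i its last residue.
#'
#' @param trace A `calpha_trace`.
#' @param annotation A `segment_annotation` built on the same trace.
#' @return A tibble of class `joint_set` with 2n rows: `joint`, `strand`,
#'   `terminus` ("first"/"last"), `resno`, `ins`, `res_id`, `x`, `y`, `z`.
#' @export
extract_joints <- function(trace, annotation) {
  s <- filter(annotation, .data$kind == "strand")
  pos <- as.vector(rbind(s$start_pos, s$end_pos))
  if (anyNA(pos) || any(pos < 1 | pos > nrow(trace))) {
    bj_abort("strand terminus outside trace", "missing_terminus")
  }
  n <- nrow(s)
  out <- tibble(
    joint = seq_len(2 * n),
    strand = rep(seq_len(n), each = 2),
    terminus = rep(c("first", "last"), n),
    resno = trace$resno[pos], ins = trace$ins[pos],
    res_id = format_res_id(trace$resno[pos], trace$ins[pos]),
    x = trace$x[pos], y = trace$y[pos], z = trace$z[pos]
  )
  attr(out, "n_strands") <- n
  attr(out, "chain") <- attr(annotation, "chain") %||% trace$chain[1]
  class(out) <- c("joint_set", class(out))
  out
}

#' Signed torsion angle of four points
#'
#' The standard right-handed torsion: with bond vectors `b1 = p2 - p1`,
#' `b2 = p3 - p2`, `b3 = p4 - p3`,
#' `angle = atan2(|b2| * b1 . (b2 x b3), (b1 x b2) . (b2 x b3))` in degrees.
#' Positive angles are clockwise rotations of `p4` relative to `p1` when
#' viewed from `p2` towards `p3`. The domain is (-180, +180]: an exact -180
#' is normalized to +180 so that sign classification is total.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' signed_dihedral(c(0, 0, 0), c(0, 4, 0), c(2, 4, 0), c(2, 0, 0)) # 0
#' signed_dihedral(c(0, 0, 0), c(0, 4, 0), c(2, 0, 0), c(2, 4, 0)) # 180
#' signed_dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)) # 90
#' @export
signed_dihedral <- function(p1, p2, p3, p4) {
  P <- rbind(p1, p2, p3, p4)
  if (!is.numeric(P) || ncol(P) != 3 || anyNA(P)) {
    bj_abort("points must be finite numeric 3-vectors", "bad_config")
  }
  torsion_window(P[1, ], P[2, ], P[3, ], P[4, ])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Degeneracy rule: after normalizing each bond vector to unit length, a
# cross-product norm below 1e-9 means a zero-length bond or an exactly
# collinear triple; the torsion is then undefined.
torsion_window <- function(p1, p2, p3, p4, tol = 1e-9) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- sqrt(sum(b1^2)); n2 <- sqrt(sum(b2^2)); n3 <- sqrt(sum(b3^2))
  if (n1 < tol || n2 < tol || n3 < tol) {
    bj_abort("coincident joint points: zero-length bond vector",
             "degenerate_geometry")
  }
  u1 <- b1 / n1; u2 <- b2 / n2; u3 <- b3 / n3
  c12 <- cross3(u1, u2); c23 <- cross3(u2, u3)
  if (sqrt(sum(c12^2)) < tol || sqrt(sum(c23^2)) < tol) {
    bj_abort("collinear joint points: torsion undefined",
             "degenerate_geometry")
  }
  ang <- atan2(sum(u1 * c23), sum(c12 * c23)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Compute the alternating beta/gamma descriptor from a joint set
#'
#' Angle k (1-based) is the signed torsion of joints (P_k, P_k+1, P_k+2,
#' P_k+3) for k = 1..2n-3. Odd k are beta-type (beta_(k+1)/2), even k are
#' gamma-type (gamma_k/2), so a structure with n strands contributes n-1
#' beta and n-2 gamma angles.
#'
#' @param joints A `joint_set` from [extract_joints()].
#' @param flip_sign If `TRUE`, negate every angle. The clockwise/positive
#'   convention of published projection drawings is not pinned algebraically;
#'   this flag flips the whole descriptor if the opposite convention is
#'   needed for comparison.
#' @param structure_id Optional label recorded with every angle; useful when
#'   binding descriptors of many structures for [aggregate_patterns()].
#' @return A tibble of class `barrel_descriptor` with 2n-3 rows:
#'   `structure_id`, `n_strands`, `index`, `type` ("beta"/"gamma"),
#'   `type_index`, `label` (e.g. "beta_1"), `angle` (degrees in (-180, 180]).
#' @export
compute_descriptor <- function(joints, flip_sign = FALSE,
                               structure_id = NA_character_) {
  n <- attr(joints, "n_strands")
  if (is.null(n) || n < 2) {
    bj_abort("joint set must come from at least 2 strands", "domain")
  }
  P <- as.matrix(joints[, c("x", "y", "z")])
  k_max <- 2L * n - 3L
  angles <- vapply(seq_len(k_max), function(k) {
    lbl <- angle_label(k)
    tryCatch(
      torsion_window(P[k, ], P[k + 1, ], P[k + 2, ], P[k + 3, ]),
      bj_degenerate_geometry = function(e) {
        bj_abort(paste0("degenerate joint quadruple for angle ", lbl, ": ",
                        conditionMessage(e)), "degenerate_geometry")
      }
    )
  }, numeric(1))
  if (flip_sign) {
    angles <- -angles
    angles[angles <= -180] <- angles[angles <= -180] + 360
  }
  k <- seq_len(k_max)
  out <- tibble(
    structure_id = structure_id,
    n_strands = as.integer(n),
    index = k,
    type = ifelse(k %% 2 == 1, "beta", "gamma"),
    type_index = ifelse(k %% 2 == 1, (k + 1) %/% 2, k %/% 2),
    label = angle_label(k),
    angle = angles
  )
  class(out) <- c("barrel_descriptor", class(out))
  out
}

angle_label <- function(k) {
  ifelse(k %% 2 == 1,
         paste0("beta_", (k + 1) %/% 2),
         paste0("gamma_", k %/% 2))
}

#' Expected number of beta- and gamma-type angles for n strands
#'
#' A structure with n strands has 2n joints and 2n-3 window torsions:
#' n-1 beta-type and n-2 gamma-type (0 when n = 2).
#'
#' @param n_strands Integer vector of strand counts, each >= 2.
#' @return A tibble with columns `n_strands`, `n_beta`, `n_gamma`.
#' @examples
#' expected_counts(c(4, 8, 12))
#' @export
expected_counts <- function(n_strands) {
  n <- as.integer(n_strands)
  if (length(n) == 0 || anyNA(n) || any(n < 2)) {
    bj_abort("n_strands must be integers >= 2", "domain")
  }
  tibble(n_strands = n, n_beta = n - 1L, n_gamma = pmax(n - 2L, 0L))
}

#' @export
print.barrel_descriptor <- function(x, ...) {
  cat("<barrel_descriptor> ", x$n_strands[1], " strands, ",
      sum(x$type == "beta"), " beta + ", sum(x$type == "gamma"),
      " gamma angles\n", sep = "")
  NextMethod()
}

#' Tidy a descriptor into an angle table with signs and quadrants
#'
#' @param x A `barrel_descriptor`.
#' @param ... Unused.
#' @return The descriptor tibble with `sign` and `quadrant` columns added.
#' @method tidy barrel_descriptor
#' @export
tidy.barrel_descriptor <- function(x, ...) {
  out <- as_tibble(x)
  out$sign <- sign_of(out$angle)
  out$quadrant <- quadrant_of(out$angle)
  out
}

#' One-row summary of a descriptor
#'
#' @param x A `barrel_descriptor`.
#' @param ... Unused.
#' @return A one-row tibble: strand/angle counts, per-type means and the
#'   fraction of positive angles.
#' @method glance barrel_descriptor
#' @export
glance.barrel_descriptor <- function(x, ...) {
  b <- x$angle[x$type == "beta"]; g <- x$angle[x$type == "gamma"]
  tibble(
    n_strands = x$n_strands[1],
    n_beta = length(b), n_gamma = length(g),
    mean_beta = mean(b), mean_gamma = if (length(g)) mean(g) else NA_real_,
    frac_positive = mean(x$angle >= 0)
  )
}
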