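# Docking-geometry comparison of two-domain receptor complexes: hinge
# (elbow) angles, per-domain twist differences after platform alignment,
# centre-of-mass shifts along the peptide-binding groove, and the
# domain-wise superposition r.m.s.d. values that accompany them.

# Intrinsic "up" direction of a complex: from the platform C-alpha centroid
# toward the receptor C-alpha centroid. Used to fix the e2 sign of domain
# frames; being defined from the coordinates themselves it is invariant
# under rigid motion of the whole complex.
model_up <- function(model) {
  up <- colMeans(model_part(model, "kir")$xyz) -
    colMeans(model_part(model, "platform")$xyz)
  up / sqrt(sum(up^2))
}

domain_frame_of <- function(model, domain = c("d1", "d2")) {
  domain <- match.arg(domain)
  principal_frame(model_part(model, domain), up = model_up(model))
}

#' Hinge (elbow) angle of a two-domain receptor
#'
#' The angle between the long principal axes (`e1`) of the D1 and D2 domain
#' C-alpha clouds, using the orientation conventions of
#' [principal_frame()]. For KIR2D receptors docked on HLA-C this is the
#' interdomain elbow angle, close to 77 degrees.
#'
#' @param model A `complex_model`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
hinge_angle <- function(model) {
  stopifnot(inherits(model, "complex_model"))
  f1 <- domain_frame_of(model, "d1")
  f2 <- domain_frame_of(model, "d2")
  d <- sum(f1$axes[, "e1"] * f2$axes[, "e1"])
  acos(max(-1, min(1, d))) * 180 / pi
}

# Platform alignment: rigid transform that takes cmp onto ref using paired
# platform C-alpha atoms. Returns the transform and the platform rmsd.
platform_alignment <- function(ref, cmp) {
  pr <- pair_common_residues(model_part(ref, "platform"),
                             model_part(cmp, "platform"))
  fit <- kabsch_superpose(pr$b, pr$a)    # cmp (mobile) onto ref (target)
  list(transform = fit$transform, rmsd = fit$rmsd)
}

# Domain rotation of cmp relative to ref after platform alignment:
# the Kabsch rotation mapping ref's domain C-alphas onto aligned cmp's.
domain_rotation <- function(ref, cmp, domain, align) {
  pd <- pair_common_residues(model_part(ref, domain),
                             model_part(cmp, domain))
  cmp_aligned <- apply_transform(pd$b, align$transform)
  kabsch_superpose(pd$a, cmp_aligned)
}

#' Twist difference of a receptor domain between two complexes
#'
#' Both complexes are first aligned on the HLA platform (paired C-alpha
#' atoms of `platform_range`, default residues 1-180). The Kabsch rotation
#' mapping the reference domain onto the aligned comparison domain is then
#' decomposed about the reference domain's twist axis (`e3`, the short
#' inertia axis perpendicular to the hinge axis); the twist component is
#' returned.
#'
#' @param ref,cmp `complex_model`s sharing the platform residue range after
#'   pairing.
#' @param domain `"d1"` or `"d2"`.
#' @return Signed twist angle in degrees (report magnitudes for comparison
#'   with published values).
#' @export
twist_difference <- function(ref, cmp, domain = c("d1", "d2")) {
  domain <- match.arg(domain)
  align <- platform_alignment(ref, cmp)
  rot <- domain_rotation(ref, cmp, domain, align)
  axis <- domain_frame_of(ref, domain)$axes[, "e3"]
  swing_twist(rot$transform$R, axis)$twist_deg
}

#' Centre-of-mass shift of a domain along the peptide-binding groove
#'
#' After platform alignment, projects the displacement of the domain
#' C-alpha centroid (comparison minus reference) onto the groove axis: the
#' unit vector from the reference peptide's first-position C-alpha to its
#' last-position C-alpha. Positive values point toward the peptide
#' C-terminus.
#'
#' @inheritParams twist_difference
#' @return Signed shift in Angstrom.
#' @export
com_shift_along_groove <- function(ref, cmp, domain = c("d1", "d2")) {
  domain <- match.arg(domain)
  align <- platform_alignment(ref, cmp)
  pep <- model_part(ref, "peptide")
  g <- pep$xyz[nrow(pep$xyz), ] - pep$xyz[1, ]
  g <- g / sqrt(sum(g^2))
  com_ref <- colMeans(model_part(ref, domain)$xyz)
  com_cmp <- colMeans(apply_transform(model_part(cmp, domain),
                                      align$transform)$xyz)
  sum((com_cmp - com_ref) * g)
}

#' Full docking-geometry comparison of two complexes
#'
#' Computes per-complex hinge angles and their difference, signed and
#' absolute per-domain twist differences, centre-of-mass shifts along the
#' groove axis, and platform/domain superposition r.m.s.d. values, together
#' with a conventions block recording every range and axis convention
#' applied. Deterministic given its inputs.
#'
#' @param ref,cmp `complex_model`s (reference first; published comparisons
#'   use the earlier-determined complex as reference).
#' @return An object of class `geometry_comparison`.
#' @export
compare_complexes <- function(ref, cmp) {
  stopifnot(inherits(ref, "complex_model"), inherits(cmp, "complex_model"))
  align <- platform_alignment(ref, cmp)
  hinge_ref <- hinge_angle(ref)
  hinge_cmp <- hinge_angle(cmp)
  res <- list(hinge_ref = hinge_ref, hinge_cmp = hinge_cmp,
              delta_hinge = abs(hinge_ref - hinge_cmp))
  for (dom in c("d1", "d2")) {
    rot <- domain_rotation(ref, cmp, dom, align)
    axis <- domain_frame_of(ref, dom)$axes[, "e3"]
    tw <- swing_twist(rot$transform$R, axis)$twist_deg
    res[[paste0("delta_twist_", dom)]] <- tw
    res[[paste0("delta_twist_", dom, "_abs")]] <- abs(tw)
    res[[paste0("com_shift_", dom)]] <- com_shift_along_groove(ref, cmp, dom)
    # domain-wise superposition (independent of platform alignment)
    pd <- pair_common_residues(model_part(ref, dom), model_part(cmp, dom))
    res[[paste0("rmsd_", dom)]] <- kabsch_superpose(pd$b, pd$a)$rmsd
  }
  res$rmsd_platform <- align$rmsd
  res$conventions <- list(
    platform_range = ref$platform_range,
    d1_range = ref$d1_range, d2_range = ref$d2_range,
    ref_chains = unlist(ref$chains), cmp_chains = unlist(cmp$chains),
    twist_axis = "reference domain e3 (short inertia axis)",
    hinge = "angle between D1 and D2 long principal axes, per complex",
    e1_sign = "first-to-last residue centroid direction",
    e2_sign = "toward platform-to-receptor direction",
    groove_axis = "reference peptide P1 C-alpha to last-position C-alpha",
    alignment = "Kabsch over paired platform C-alpha atoms")
  structure(res, class = "geometry_comparison")
}

#' @export
print.geometry_comparison <- function(x, ...) {
  cat(sprintf("<geometry_comparison>\n  hinge: ref %.1f deg, cmp %.1f deg (delta %.1f)\n",
              x$hinge_ref, x$hinge_cmp, x$delta_hinge))
  cat(sprintf("  twist: D1 %+.1f deg, D2 %+.1f deg\n",
              x$delta_twist_d1, x$delta_twist_d2))
  cat(sprintf("  COM shift along groove: D1 %+.2f A, D2 %+.2f A\n",
              x$com_shift_d1, x$com_shift_d2))
  cat(sprintf("  rmsd: platform %.2f A, D1 %.2f A, D2 %.2f A\n",
              x$rmsd_platform, x$rmsd_d1, x$rmsd_d2))
  invisible(x)
}

#' One-row data frame view of a geometry comparison
#' @param x A `geometry_comparison`.
#' @param ... Unused.
#' @return A one-row data frame of the numeric fields.
#' @export
as.data.frame.geometry_comparison <- function(x, ...) {
  num <- x[vapply(x, is.numeric, logical(1))]
  as.data.frame(num)
}
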