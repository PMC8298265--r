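# Deterministic miniature systems used by the test-suite (and useful
# for quick experiments): a single uniform vessel, a symmetric
# Y-junction, a fully enumerable small structured tree, and a minimal
# artery-tree-vein-atrium coupled system.

#' Build a generic vessel network from a geometry table
#'
#' Lower-level constructor behind [build_network()]; accepts any
#' geometry table, junction list and artery-vein tree mapping, so that
#' reduced test systems use exactly the same machinery as the full
#' pulmonary network.
#'
#' @inheritParams build_network
#' @param junctions list of `c(parent, daughter1, daughter2)` name
#'   triples.
#' @param mapping named character vector artery -> vein for
#'   structured-tree interfaces (may be empty).
#' @return a `pulmo_network`.
#' @export
vessel_network <- function(geometry, dx_cm = 0.05, EhR0_mmHg = 150,
                           p0_mmHg = 0, fluid = fluid_properties(),
                           junctions = list(), mapping = character(),
                           tree_lrr = 12.4, tree_alpha = 0.91,
                           tree_beta = 0.58, tree_r_min = 0.003) {
  .assemble_network(geometry, dx_cm, EhR0_mmHg, p0_mmHg, fluid,
                    junctions = junctions, mapping = mapping,
                    tree = list(lrr = tree_lrr, alpha = tree_alpha,
                                beta = tree_beta, r_min = tree_r_min))
}

#' Miniature test systems
#'
#' @param kind one of `"single-vessel"` (uniform artery, 10 cm),
#'   `"y-junction"` (one parent, two identical daughters),
#'   `"small-tree"` (structured-tree spec with root 0.01 cm, fully
#'   enumerable), `"coupled-minimal"` (one artery linked to one vein
#'   through a tree).
#' @param dx_cm grid spacing for the vessel fixtures.
#' @return a `pulmo_network` or (for `"small-tree"`) a [tree_spec()].
#' @export
toy_fixture <- function(kind = c("single-vessel", "y-junction",
                                 "small-tree", "coupled-minimal"),
                        dx_cm = 0.1) {
  kind <- match.arg(kind)
  switch(kind,
    "single-vessel" = vessel_network(
      data.frame(name = "V1", type = "artery", prox_diam_cm = 1.0,
                 dist_diam_cm = 1.0, length_cm = 10), dx_cm = dx_cm),
    "y-junction" = vessel_network(
      data.frame(name = c("P", "D1", "D2"), type = "artery",
                 prox_diam_cm = c(2.0, 1.4, 1.4),
                 dist_diam_cm = c(2.0, 1.4, 1.4),
                 length_cm = c(5, 4, 4)), dx_cm = dx_cm,
      junctions = list(c("P", "D1", "D2"))),
    "small-tree" = tree_spec(0.01),
    "coupled-minimal" = vessel_network(
      data.frame(name = c("A1", "V1"), type = c("artery", "vein"),
                 prox_diam_cm = c(1.5, 1.5), dist_diam_cm = c(1.4, 1.4),
                 length_cm = c(3, 3)), dx_cm = dx_cm,
      mapping = c(A1 = "V1")))
}
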