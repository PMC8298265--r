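#' Large-vessel geometry of the pulmonary network
#'
#' Proximal/distal diameters and lengths (cm) of the seven large
#' pulmonary arteries and four large veins.  For arteries "proximal"
#' faces the heart; for veins it faces the microvascular bed, so that in
#' every vessel x runs in the direction of mean flow from the proximal
#' to the distal end.
#'
#' @return data.frame with columns `name`, `type`, `prox_diam_cm`,
#'   `dist_diam_cm`, `length_cm`.
#' @export
pulmonary_geometry <- function() {
  data.frame(
    name = c("MPA", "RPA", "LPA", "RIA", "RTA", "LIA", "LTA",
             "RIPV", "RSPV", "LIPV", "LSPV"),
    type = c(rep("artery", 7), rep("vein", 4)),
    prox_diam_cm = c(3.1, 2.5, 1.8, 1.5, 1.5, 1.7, 1.4, 1.5, 1.7, 1.6, 1.5),
    dist_diam_cm = c(3.0, 1.6, 1.8, 1.5, 1.5, 1.5, 1.4, 1.5, 1.5, 1.5, 1.4),
    length_cm    = c(4.5, 5.8, 2.5, 1.6, 1.7, 1.9, 1.2, 1.6, 2.5, 1.8, 2.3),
    stringsAsFactors = FALSE)
}

# default terminal-artery-to-vein pairing for the structured trees
.default_tree_mapping <- c(RIA = "RIPV", RTA = "RSPV", LIA = "LIPV", LTA = "LSPV")

#' Build the discretised pulmonary vessel network
#'
#' Assembles the large-vessel network: MPA bifurcating into RPA and LPA,
#' each bifurcating into an interlobular and a trunk artery, with each
#' terminal artery linked to its pulmonary vein through a mirrored
#' structured tree.  The reference radius tapers linearly between the
#' proximal and distal values; all large vessels share one wall
#' stiffness.
#'
#' @param geometry geometry table as from [pulmonary_geometry()].
#' @param dx_cm target grid spacing in cm (each vessel uses the nearest
#'   spacing that divides its length exactly).
#' @param EhR0_mmHg large-vessel wall stiffness in mmHg.
#' @param p0_mmHg external pressure in mmHg.
#' @param fluid a [fluid_properties()].
#' @param tree_lrr,tree_alpha,tree_beta,tree_r_min structured-tree
#'   parameters (see [tree_spec()]).
#' @param mapping named character vector pairing each terminal artery
#'   with its vein.
#' @return an object of class `pulmo_network`.
#' @export
build_network <- function(geometry = pulmonary_geometry(), dx_cm = 0.05,
                          EhR0_mmHg = 150, p0_mmHg = 0,
                          fluid = fluid_properties(),
                          tree_lrr = 12.4, tree_alpha = 0.91,
                          tree_beta = 0.58, tree_r_min = 0.003,
                          mapping = .default_tree_mapping) {
  required <- c("MPA", "RPA", "LPA", "RIA", "RTA", "LIA", "LTA",
                "RIPV", "RSPV", "LIPV", "LSPV")
  missing <- setdiff(required, geometry$name)
  if (length(missing))
    stop("geometry table is missing vessel(s): ", paste(missing, collapse = ", "))
  geometry <- geometry[match(required, geometry$name), ]
  bad <- with(geometry, prox_diam_cm <= 0 | dist_diam_cm <= 0 | length_cm <= 0)
  if (any(bad))
    stop("non-positive dimension for vessel(s): ",
         paste(geometry$name[bad], collapse = ", "))
  .assemble_network(geometry, dx_cm, EhR0_mmHg, p0_mmHg, fluid,
                    junctions = list(c("MPA", "RPA", "LPA"),
                                     c("RPA", "RIA", "RTA"),
                                     c("LPA", "LIA", "LTA")),
                    mapping = mapping,
                    tree = list(lrr = tree_lrr, alpha = tree_alpha,
                                beta = tree_beta, r_min = tree_r_min))
}

# shared assembly for the full network and the toy fixtures
.assemble_network <- function(geometry, dx_cm, EhR0_mmHg, p0_mmHg, fluid,
                              junctions = list(), mapping = character(),
                              tree = NULL) {
  nv <- nrow(geometry)
  n <- pmax(3L, as.integer(round(geometry$length_cm / dx_cm))) + 1L
  i1 <- cumsum(n); i0 <- c(1L, utils::head(i1, -1) + 1L)
  Ntot <- sum(n)
  R0 <- numeric(Ntot); dxn <- numeric(Ntot)
  for (v in seq_len(nv)) {
    idx <- i0[v]:i1[v]
    R0[idx] <- cm_to_m(seq(geometry$prox_diam_cm[v] / 2,
                           geometry$dist_diam_cm[v] / 2,
                           length.out = n[v]))
    dxn[idx] <- cm_to_m(geometry$length_cm[v]) / (n[v] - 1L)
  }
  A0 <- pi * R0^2
  f <- rep((4 / 3) * mmHg_to_Pa(EhR0_mmHg), Ntot)
  # half-point machinery (excludes cross-vessel pairs)
  iL <- setdiff(seq_len(Ntot), i1); iR <- iL + 1L
  A0h <- (A0[iL] + A0[iR]) / 2
  dxh <- dxn[iL]
  dA0dxh <- (A0[iR] - A0[iL]) / dxh
  # interior nodes and their adjacent half intervals
  ii <- setdiff(seq_len(Ntot), c(i0, i1))
  hof <- integer(Ntot); hof[iL] <- seq_along(iL)  # half idx of (g, g+1)
  hl <- hof[ii - 1L]; hr <- hof[ii]
  vess <- data.frame(name = geometry$name, type = geometry$type,
                     n = n, i0 = i0, i1 = i1,
                     dx_m = cm_to_m(geometry$length_cm) / (n - 1L),
                     length_cm = geometry$length_cm,
                     prox_r_cm = geometry$prox_diam_cm / 2,
                     dist_r_cm = geometry$dist_diam_cm / 2,
                     stringsAsFactors = FALSE)
  vid <- function(nm) match(nm, vess$name)
  jn <- NULL
  if (length(junctions)) {
    jn <- list(
      p_end = vapply(junctions, function(j) i1[vid(j[1])], integer(1)),
      d1_start = vapply(junctions, function(j) i0[vid(j[2])], integer(1)),
      d2_start = vapply(junctions, function(j) i0[vid(j[3])], integer(1)))
  }
  ifc <- NULL
  if (length(mapping)) {
    arteries <- names(mapping); veins <- unname(mapping)
    ifc <- list(
      artery = arteries, vein = veins,
      a_end = vapply(arteries, function(nm) i1[vid(nm)], integer(1),
                     USE.NAMES = FALSE),
      v_start = vapply(veins, function(nm) i0[vid(nm)], integer(1),
                       USE.NAMES = FALSE),
      r_root_a = vapply(arteries, function(nm) vess$dist_r_cm[vid(nm)],
                        numeric(1), USE.NAMES = FALSE),
      r_root_v = vapply(veins, function(nm) vess$prox_r_cm[vid(nm)],
                        numeric(1), USE.NAMES = FALSE))
  }
  structure(list(
    vessels = vess, fluid = fluid, p0 = mmHg_to_Pa(p0_mmHg),
    EhR0_mmHg = EhR0_mmHg,
    R0 = R0, A0 = A0, f = f, sf = sqrt(f / (2 * fluid$rho)),
    half = list(iL = iL, iR = iR, A0h = A0h, dxh = dxh,
                fh = (f[iL] + f[iR]) / 2, dA0dxh = dA0dxh),
    interior = list(ii = ii, hl = hl, hr = hr, dxi = dxn[ii]),
    junctions = jn, interfaces = ifc, tree = tree,
    inlet = 1L,
    outlets = if (length(mapping)) vapply(unname(mapping), function(nm) i1[vid(nm)], integer(1)) else integer(),
    midpoints = i0 + (n - 1L) %/% 2L
  ), class = "pulmo_network")
}

#' @export
print.pulmo_network <- function(x, ...) {
  cat("pulmo_network:", nrow(x$vessels), "vessels,",
      length(x$A0), "grid nodes\n")
  cat(" vessels:", paste(x$vessels$name, collapse = " "), "\n")
  if (!is.null(x$interfaces))
    cat(" structured-tree interfaces:",
        paste(x$interfaces$artery, x$interfaces$vein, sep = "-", collapse = ", "), "\n")
  invisible(x)
}
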