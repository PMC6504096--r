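# Idealized heavy-atom residue templates.
#
# Side chains are built from internal coordinates (bond, angle, torsion
# against three previously placed atoms) with literature-typical values,
# expressed in the local backbone frame used for grafting: CA at the
# origin, N along +x, C in the xy-plane (positive y). Charges are a
# coarse bundled scheme: formal charges on ionisable groups, small
# compensated dipoles on polar groups, zero elsewhere; radii are Bondi.

# place atom D from reference positions a, b, c with bond |cD|,
# angle b-c-D (deg) and torsion a-b-c-D (deg)
.nerf <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  m <- c - b; m <- m / sqrt(sum(m^2))
  ab <- b - a
  n <- c(ab[2] * m[3] - ab[3] * m[2],
         ab[3] * m[1] - ab[1] * m[3],
         ab[1] * m[2] - ab[2] * m[1])
  n <- n / sqrt(sum(n^2))
  p <- c(n[2] * m[3] - n[3] * m[2],
         n[3] * m[1] - n[1] * m[3],
         n[1] * m[2] - n[2] * m[1])
  c + bond * (-m * cos(th) + p * sin(th) * cos(ph) + n * sin(th) * sin(ph))
}

# side-chain internal coordinates beyond CB: name, refs A/B/C, bond, angle, torsion
.SIDECHAIN_ZMAT <- list(
  ALA = list(),
  GLY = NULL, # no CB
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.808, 114.4, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  LEU = list(c("CG", "N", "CA", "CB", 1.530, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.521, 110.5, 180),
             c("CD2", "CA", "CB", "CG", 1.521, 110.5, 60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.520, 114.0, 180),
             c("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = list(c("CG", "N", "CA", "CB", 1.495, 104.5, 30),
             c("CD", "CA", "CB", "CG", 1.507, 106.0, -35)),
  PHE = list(c("CG", "N", "CA", "CB", 1.502, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0)),
  TYR = list(c("CG", "N", "CA", "CB", 1.502, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.390, 120.0, 0),
             c("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(c("CG", "N", "CA", "CB", 1.495, 114.0, 180),
             c("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
             c("CD2", "CA", "CB", "CG", 1.433, 126.6, -90),
             c("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             c("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
             c("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
             c("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
             c("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
             c("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  ASP = list(c("CG", "N", "CA", "CB", 1.516, 113.0, 180),
             c("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = list(c("CG", "N", "CA", "CB", 1.516, 113.0, 180),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.530, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.516, 113.0, 180),
             c("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = list(c("CG", "N", "CA", "CB", 1.530, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.516, 113.0, 180),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.530, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.530, 114.0, 180),
             c("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.492, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.380, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.354, 131.1, -90),
             c("CE1", "CB", "CG", "ND1", 1.326, 109.3, 180),
             c("NE2", "CB", "CG", "CD2", 1.373, 107.2, 180))
)

.BACKBONE_CHARGES <- c(N = -0.30, CA = 0.25, C = 0.55, O = -0.50)

.SIDECHAIN_CHARGES <- list(
  SER = c(CB = 0.40, OG = -0.40),
  THR = c(CB = 0.40, OG1 = -0.40),
  CYS = c(CB = 0.20, SG = -0.20),
  ASP = c(CG = 0.60, OD1 = -0.80, OD2 = -0.80),
  GLU = c(CD = 0.60, OE1 = -0.80, OE2 = -0.80),
  ASN = c(CG = 0.70, OD1 = -0.55, ND2 = -0.15),
  GLN = c(CD = 0.70, OE1 = -0.55, NE2 = -0.15),
  LYS = c(CE = 0.20, NZ = 0.80),
  ARG = c(NE = -0.10, CZ = 0.40, NH1 = 0.35, NH2 = 0.35),
  HIS = c(ND1 = -0.35, CE1 = 0.35),
  TYR = c(CZ = 0.40, OH = -0.40),
  TRP = c(NE1 = -0.20, CD1 = 0.10, CE2 = 0.10)
)

.build_template <- function(resname) {
  # backbone in the local frame: CA at origin, N along +x, C in xy-plane
  pos <- list(
    N = c(1.458, 0, 0),
    CA = c(0, 0, 0),
    C = 1.525 * c(cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
  )
  pos$O <- .nerf(pos$N, pos$CA, pos$C, 1.231, 120.5, 0)
  names_bb <- c("N", "CA", "C", "O")
  sc_names <- character()
  if (resname != "GLY") {
    pos$CB <- .nerf(pos$C, pos$N, pos$CA, 1.530, 110.5, -122.5)
    sc_names <- "CB"
    for (row in .SIDECHAIN_ZMAT[[resname]]) {
      nm <- row[1]
      pos[[nm]] <- .nerf(pos[[row[2]]], pos[[row[3]]], pos[[row[4]]],
                         as.numeric(row[5]), as.numeric(row[6]),
                         as.numeric(row[7]))
      sc_names <- c(sc_names, nm)
    }
  }
  all_names <- c(names_bb, sc_names)
  xyz <- unname(do.call(rbind, lapply(pos[all_names], unname)))
  elem <- element_of(all_names)
  q <- unname(.BACKBONE_CHARGES[all_names])
  q[is.na(q)] <- 0
  sc_q <- .SIDECHAIN_CHARGES[[resname]]
  if (!is.null(sc_q)) {
    idx <- match(names(sc_q), all_names)
    q[idx] <- unname(sc_q)
  }
  tibble(residue_name = resname, atom_name = all_names, element = elem,
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = q,
         radius = unname(BONDI_RADII[elem]),
         backbone = all_names %in% names_bb)
}

#' Idealized residue template library
#'
#' Heavy-atom templates for the 20 standard amino acids, built from
#' idealized internal coordinates in a local N-CA-C backbone frame
#' (CA at the origin, N along +x, C in the xy-plane). Each template
#' carries the coarse bundled per-atom charges and Bondi radii used for
#' side-chain grafting. The result is memoised.
#'
#' @return named list of 20 tibbles with columns `residue_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `charge`, `radius`,
#'   `backbone`.
#' @export
residue_templates <- function() {
  if (!is.null(.rr_cache$templates)) return(.rr_cache$templates)
  resnames <- sort(unname(AA_ONE_TO_THREE))
  out <- setNames(lapply(resnames, .build_template), resnames)
  .rr_cache$templates <- out
  out
}

# orthonormal local frame from backbone positions: rows are x, y, z axes
.backbone_frame <- function(n_pos, ca_pos, c_pos) {
  xa <- n_pos - ca_pos
  xa <- xa / sqrt(sum(xa^2))
  cc <- c_pos - ca_pos
  za <- c(xa[2] * cc[3] - xa[3] * cc[2],
          xa[3] * cc[1] - xa[1] * cc[3],
          xa[1] * cc[2] - xa[2] * cc[1])
  za <- za / sqrt(sum(za^2))
  ya <- c(za[2] * xa[3] - za[3] * xa[2],
          za[3] * xa[1] - za[1] * xa[3],
          za[1] * xa[2] - za[2] * xa[1])
  rbind(xa, ya, za)
}
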