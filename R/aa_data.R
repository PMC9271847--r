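# Amino-acid reference data: name maps, heavy-atom composition and
# internal-coordinate (Z-matrix) side-chain templates used by the rotamer
# placer.  Geometry is ideal-bond/angle textbook geometry; torsions that are
# sampled by the placer are tagged "chi1"/"chi2", deeper torsions are fixed.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# common modified residues mapped to their parent amino acid on parsing
AA_MODIFIED_MAP <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", MLY = "LYS", CME = "CYS", PCA = "GLU"
)

# residue names treated as solvent/ions and silently dropped
SOLVENT_RESIDUES <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN", "SO4", "PO4")

# Z-matrix side-chain templates.  Each row places one heavy atom `atom`
# from three previously placed atoms a-b-c (d bonded to c) with the given
# bond length (Angstrom), bond angle (degrees) and torsion.  `tors` names
# the rotatable degree of freedom ("chi1".."chi4") or "fix"; `off` is the
# offset (degrees) added to that torsion.  chi3/chi4 are held at 180 by the
# placer; proline's ring is a fixed template.
aa_zrow <- function(atom, a, b, c, bond, angle, tors, off = 0) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
             tors = tors, off = off, stringsAsFactors = FALSE)
}

# CB is common to all non-glycine residues (improper torsion off the
# backbone frame; value tuned for L-amino-acid chirality)
CB_ROW <- aa_zrow("CB", "C", "N", "CA", 1.53, 110.5, "fix", 122.5)

AA_SIDECHAIN_TEMPLATES <- local({
  t <- list()
  t$GLY <- NULL
  t$ALA <- CB_ROW
  t$SER <- rbind(CB_ROW, aa_zrow("OG",  "N", "CA", "CB", 1.42, 110.8, "chi1"))
  t$CYS <- rbind(CB_ROW, aa_zrow("SG",  "N", "CA", "CB", 1.81, 114.4, "chi1"))
  t$THR <- rbind(CB_ROW,
                 aa_zrow("OG1", "N", "CA", "CB", 1.43, 109.6, "chi1"),
                 aa_zrow("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1", -120))
  t$VAL <- rbind(CB_ROW,
                 aa_zrow("CG1", "N", "CA", "CB", 1.52, 110.5, "chi1"),
                 aa_zrow("CG2", "N", "CA", "CB", 1.52, 110.5, "chi1", 122))
  t$LEU <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.53, 116.3, "chi1"),
                 aa_zrow("CD1", "CA", "CB", "CG", 1.52, 110.7, "chi2"),
                 aa_zrow("CD2", "CA", "CB", "CG", 1.52, 110.7, "chi2", 122))
  t$ILE <- rbind(CB_ROW,
                 aa_zrow("CG1", "N",  "CA", "CB",  1.53, 110.4, "chi1"),
                 aa_zrow("CG2", "N",  "CA", "CB",  1.52, 110.5, "chi1", -122),
                 aa_zrow("CD1", "CA", "CB", "CG1", 1.52, 113.9, "chi2"))
  t$MET <- rbind(CB_ROW,
                 aa_zrow("CG", "N",  "CA", "CB", 1.52, 114.1, "chi1"),
                 aa_zrow("SD", "CA", "CB", "CG", 1.80, 112.7, "chi2"),
                 aa_zrow("CE", "CB", "CG", "SD", 1.79, 100.9, "chi3"))
  t$PRO <- rbind(aa_zrow("CB", "C", "N",  "CA", 1.53, 103.0, "fix", 115),
                 aa_zrow("CG", "N", "CA", "CB", 1.49, 104.5, "fix", 30),
                 aa_zrow("CD", "CA", "CB", "CG", 1.50, 106.1, "fix", -35))
  t$PHE <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB",  1.50, 113.8, "chi1"),
                 aa_zrow("CD1", "CA", "CB", "CG",  1.39, 120.8, "chi2"),
                 aa_zrow("CD2", "CA", "CB", "CG",  1.39, 120.8, "chi2", 180),
                 aa_zrow("CE1", "CB", "CG", "CD1", 1.39, 120.8, "fix", 180),
                 aa_zrow("CE2", "CB", "CG", "CD2", 1.39, 120.8, "fix", 180),
                 aa_zrow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, "fix", 0))
  t$TYR <- rbind(t$PHE,
                 aa_zrow("OH", "CD1", "CE1", "CZ", 1.38, 119.9, "fix", 180))
  t$TRP <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",   "CA",  "CB",  1.50, 113.6, "chi1"),
                 aa_zrow("CD1", "CA",  "CB",  "CG",  1.37, 126.9, "chi2"),
                 aa_zrow("CD2", "CA",  "CB",  "CG",  1.43, 126.7, "chi2", 180),
                 aa_zrow("NE1", "CB",  "CG",  "CD1", 1.38, 110.2, "fix", 180),
                 aa_zrow("CE2", "CB",  "CG",  "CD2", 1.41, 107.2, "fix", 180),
                 aa_zrow("CE3", "CD1", "CG",  "CD2", 1.40, 133.9, "fix", 180),
                 aa_zrow("CZ2", "CG",  "CD2", "CE2", 1.40, 122.4, "fix", 180),
                 aa_zrow("CZ3", "CG",  "CD2", "CE3", 1.39, 118.8, "fix", 180),
                 aa_zrow("CH2", "CD2", "CE3", "CZ3", 1.40, 121.2, "fix", 0))
  t$ASP <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.52, 112.6, "chi1"),
                 aa_zrow("OD1", "CA", "CB", "CG", 1.25, 118.4, "chi2"),
                 aa_zrow("OD2", "CA", "CB", "CG", 1.25, 118.4, "chi2", 180))
  t$ASN <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.52, 112.6, "chi1"),
                 aa_zrow("OD1", "CA", "CB", "CG", 1.23, 120.8, "chi2"),
                 aa_zrow("ND2", "CA", "CB", "CG", 1.33, 116.7, "chi2", 180))
  t$GLU <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
                 aa_zrow("CD",  "CA", "CB", "CG", 1.52, 112.6, "chi2"),
                 aa_zrow("OE1", "CB", "CG", "CD", 1.25, 118.4, "chi3"),
                 aa_zrow("OE2", "CB", "CG", "CD", 1.25, 118.4, "chi3", 180))
  t$GLN <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
                 aa_zrow("CD",  "CA", "CB", "CG", 1.52, 112.6, "chi2"),
                 aa_zrow("OE1", "CB", "CG", "CD", 1.23, 120.8, "chi3"),
                 aa_zrow("NE2", "CB", "CG", "CD", 1.33, 116.7, "chi3", 180))
  t$HIS <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB",  1.49, 113.8, "chi1"),
                 aa_zrow("ND1", "CA", "CB", "CG",  1.38, 122.7, "chi2"),
                 aa_zrow("CD2", "CA", "CB", "CG",  1.35, 131.0, "chi2", 180),
                 aa_zrow("CE1", "CB", "CG", "ND1", 1.32, 109.3, "fix", 180),
                 aa_zrow("NE2", "CB", "CG", "CD2", 1.37, 107.2, "fix", 180))
  t$LYS <- rbind(CB_ROW,
                 aa_zrow("CG", "N",  "CA", "CB", 1.52, 114.1, "chi1"),
                 aa_zrow("CD", "CA", "CB", "CG", 1.52, 111.3, "chi2"),
                 aa_zrow("CE", "CB", "CG", "CD", 1.52, 111.3, "chi3"),
                 aa_zrow("NZ", "CG", "CD", "CE", 1.49, 111.9, "chi4"))
  t$ARG <- rbind(CB_ROW,
                 aa_zrow("CG",  "N",  "CA", "CB", 1.52, 114.1, "chi1"),
                 aa_zrow("CD",  "CA", "CB", "CG", 1.52, 111.3, "chi2"),
                 aa_zrow("NE",  "CB", "CG", "CD", 1.46, 112.0, "chi3"),
                 aa_zrow("CZ",  "CG", "CD", "NE", 1.33, 124.2, "chi4"),
                 aa_zrow("NH1", "CD", "NE", "CZ", 1.33, 120.0, "fix", 0),
                 aa_zrow("NH2", "CD", "NE", "CZ", 1.33, 120.0, "fix", 180))
  t
})

# heavy side-chain atom names per residue (template order)
aa_sidechain_atoms <- function(aa3) {
  tmpl <- AA_SIDECHAIN_TEMPLATES[[aa3]]
  if (is.null(tmpl)) character(0) else tmpl$atom
}

# number of sampled chi angles for a residue (chi1/chi2 only; deeper fixed)
aa_n_sampled_chis <- function(aa3) {
  tmpl <- AA_SIDECHAIN_TEMPLATES[[aa3]]
  if (is.null(tmpl)) return(0L)
  length(intersect(c("chi1", "chi2"), tmpl$tors))
}

aa_one_to_three <- function(aa1) {
  out <- AA_ONE_TO_THREE[aa1]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    rp_stop("InvalidAlphabet",
            sprintf("invalid amino-acid code '%s' at position %d", aa1[bad], bad))
  }
  unname(out)
}

aa_three_to_one <- function(aa3) {
  mapped <- ifelse(aa3 %in% names(AA_MODIFIED_MAP), AA_MODIFIED_MAP[aa3], aa3)
  out <- AA_THREE_TO_ONE[mapped]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    rp_stop("NonStandardResidue",
            sprintf("non-standard residue '%s' at position %d", aa3[bad], bad))
  }
  unname(out)
}
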