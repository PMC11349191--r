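# Donor/acceptor chemistry of the standard amino acids. Keys are
# "RESNAME|ATOMNAME"; backbone entries are shared by all residues.

side_chain_roles <- c(
  "SER|OG"  = "both", "THR|OG1" = "both", "TYR|OH" = "both",
  "ASP|OD1" = "acceptor", "ASP|OD2" = "acceptor",
  "GLU|OE1" = "acceptor", "GLU|OE2" = "acceptor",
  "ASN|OD1" = "acceptor", "ASN|ND2" = "donor",
  "GLN|OE1" = "acceptor", "GLN|NE2" = "donor",
  "LYS|NZ"  = "donor",
  "ARG|NE"  = "donor", "ARG|NH1" = "donor", "ARG|NH2" = "donor",
  "HIS|ND1" = "both", "HIS|NE2" = "both",
  "HSD|ND1" = "both", "HSD|NE2" = "both",
  "HSE|ND1" = "both", "HSE|NE2" = "both",
  "TRP|NE1" = "donor",
  "CYS|SG"  = "both", "MET|SD"  = "acceptor"
)

STANDARD_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "HSD", "HSE", "ILE", "LEU", "LYS",
                       "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
                       "VAL")

# Donor atoms whose hydrogen position is rotamer-dependent; in hydrogen-less
# inputs these fall back to distance-only acceptance rather than getting a
# fabricated hydrogen.
ROTATABLE_DONOR <- c("SER|OG", "THR|OG1", "TYR|OH", "LYS|NZ", "CYS|SG")

#' Assign hydrogen-bond donor/acceptor roles to every atom
#'
#' Water oxygen is both donor and acceptor. Protein N/O/S atoms are looked
#' up in a built-in residue chemistry table (backbone N donates, backbone
#' O/OXT accept; Ser/Thr/Tyr hydroxyls and His/Cys do both; carboxylates
#' and Met SD accept; Lys/Arg/Trp side-chain nitrogens donate). N/O/S atoms
#' of unrecognised residues are conservatively assigned "both", with one
#' warning per residue name.
#'
#' @param structure a `wb_structure`.
#' @return character vector, one of `"donor"`, `"acceptor"`, `"both"`,
#'   `"none"` per atom.
#' @export
assign_roles <- function(structure) {
  a <- structure$atoms
  roles <- rep("none", nrow(a))
  polar <- !a$is_hydrogen & a$element %in% c("N", "O", "S")

  wat_o <- a$is_water & a$element == "O"
  roles[wat_o] <- "both"

  prot <- polar & !a$is_water
  nm <- toupper(trimws(a$name))
  res <- toupper(trimws(a$resname))
  known <- res %in% STANDARD_RESNAMES

  bb <- prot & known & nm == "N"
  roles[bb] <- ifelse(res[bb] == "PRO", "none", "donor")
  roles[prot & known & nm %in% c("O", "OXT")] <- "acceptor"
  key <- paste(res, nm, sep = "|")
  hit <- prot & known & key %in% names(side_chain_roles)
  roles[hit] <- unname(side_chain_roles[key[hit]])

  unknown <- prot & !known
  if (any(unknown)) {
    for (rn in unique(res[unknown]))
      warning(sprintf(
        "residue '%s' is not in the chemistry table; its N/O/S atoms are treated as donor+acceptor",
        rn), call. = FALSE)
    roles[unknown] <- "both"
  }
  roles
}

# Hydrogens covalently attached to heavy atom `i`: same residue, within
# 1.25 Angstrom in the given frame.
attached_hydrogens <- function(structure, xyz, i) {
  a <- structure$atoms
  same <- which(a$is_hydrogen & a$chain == a$chain[i] &
                a$resnum == a$resnum[i] & a$insert == a$insert[i])
  if (!length(same)) return(integer(0))
  d2 <- colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2)
  same[d2 <= 1.25^2]
}
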