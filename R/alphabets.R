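# Residue alphabets and per-amino-acid descriptor tables.

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Modified residues mapped to their parent one-letter code. Anything not
# listed here or in AA3 becomes 'X' and is later removed by the X filter.
AA3_MODIFIED <- c(MSE = "M", SEC = "C", PYL = "K", MLY = "K", M3L = "K",
                  CSO = "C", CSD = "C", CME = "C", OCS = "C", PTR = "Y",
                  SEP = "S", TPO = "T", HYP = "P", KCX = "K", LLP = "K",
                  FME = "M", HIC = "H", NEP = "H", ALY = "K", PCA = "E")

DNA_CODES <- c("DA", "DC", "DG", "DT", "DI")
RNA_CODES <- c("A", "C", "G", "U", "I")

#' Convert three-letter residue names to one-letter codes
#'
#' Standard amino acids and a fixed table of common modified residues
#' (e.g. MSE -> M) are mapped to their parent code; nucleotide codes map to
#' their base letter; anything else becomes `"X"`.
#'
#' @param resnames Character vector of residue names (e.g. `"ALA"`, `"MSE"`,
#'   `"DA"`).
#' @return Character vector of single letters.
#' @export
residue_one_letter <- function(resnames) {
  resnames <- toupper(trimws(resnames))
  out <- unname(AA3[resnames])
  mod <- is.na(out)
  out[mod] <- unname(AA3_MODIFIED[resnames[mod]])
  na_res <- is.na(out) & resnames %in% c(DNA_CODES, RNA_CODES)
  out[na_res] <- sub("^D", "", resnames[na_res])
  out[is.na(out)] <- "X"
  out
}

# Physicochemical descriptors of the 20 amino acids, used for the central
# residue of each feature vector: Kyte-Doolittle hydropathy rescaled to
# [-1, 1]; net side-chain charge at pH 7 (His 0.5); polar flag; side-chain
# volume rescaled by Trp; hydrogen-bonding side-chain flag. 'X' and padding
# get all zeros.
aa_physchem_table <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  vol <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
           Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
           L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
           S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  charge <- stats::setNames(rep(0, 20), AA1)
  charge[c("K", "R")] <- 1; charge["H"] <- 0.5
  charge[c("D", "E")] <- -1
  polar <- stats::setNames(as.numeric(AA1 %in%
    c("S", "T", "C", "Y", "N", "Q", "D", "E", "K", "R", "H")), AA1)
  hbond <- stats::setNames(as.numeric(AA1 %in%
    c("S", "T", "Y", "N", "Q", "D", "E", "K", "R", "H", "W")), AA1)
  m <- cbind(hydropathy = kd[AA1] / 4.5,
             charge     = charge[AA1],
             polar      = polar[AA1],
             volume     = vol[AA1] / 227.8,
             hbond      = hbond[AA1])
  rownames(m) <- AA1
  m
}
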