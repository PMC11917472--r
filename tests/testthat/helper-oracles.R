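# Independent oracles used across the suite. These deliberately share no code
# with the package: the naive scanner matches base sets position by position,
# and the complement table is written out by hand.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  v <- strsplit(x, "")[[1]]
  paste(rev(unname(ORACLE_COMP[v])), collapse = "")
}

# all 0-based start positions where `pattern` (IUPAC) matches, one strand,
# O(n*m) per-position set membership; circular inputs wrap positions
oracle_scan_one_strand <- function(seq, pattern, circular = FALSE) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  n <- length(sv)
  m <- length(pv)
  if (circular) sv <- c(sv, sv[seq_len(min(m - 1L, n))])
  last <- if (circular) n - 1L else n - m
  hits <- integer(0)
  for (s in 0:last) {
    if (s > length(sv) - m) break
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(sv[s + j] %in% ORACLE_SETS[[pv[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# both-strand naive scan: sorted unique 0-based starts (palindromes dedupe
# automatically through the union)
oracle_scan <- function(seq, pattern, circular = FALSE) {
  fwd <- oracle_scan_one_strand(seq, pattern, circular)
  rev <- oracle_scan_one_strand(seq, oracle_revcomp(pattern), circular)
  sort(unique(c(fwd, rev)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run the packaged CLI in a child Rscript that sees the same library paths
run_pipo_cli <- function(args, capture = TRUE) {
  cli <- system.file("cli", "pipo.R", package = "pipodesign")
  lib <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  suppressWarnings(system2("Rscript", c(cli, args),
                           stdout = if (capture) TRUE else FALSE,
                           stderr = if (capture) TRUE else FALSE,
                           env = lib))
}

# small shared enzyme table
test_enzymes <- function() {
  parse_enzyme_list(c("EcoRI G^AATTC", "BamHI G^GATCC", "HindIII A^AGCTT",
                      "XhoI C^TCGAG", "SalI G^TCGAC", "SacI GAGCT^C",
                      "KpnI GGTAC^C", "NheI G^CTAGC", "SpeI A^CTAGT",
                      "BglII A^GATCT"))
}

# expected insert length recomputed from first principles (independent of the
# assembly code): arms plus, for tagging, 3 six-bp sites + linker + tag gene
# normalized for the task
expected_insert_len <- function(row, params, task) {
  extra <- 0L
  if (task %in% c("tag_n", "tag_c")) {
    fpg <- params$fpg
    nf <- nchar(fpg)
    if (task == "tag_c") {
      has_stop <- nf >= 3 && substr(fpg, nf - 2, nf) %in% c("TAA", "TAG", "TGA")
      nf <- if (has_stop) nf else nf + 3L
    } else {
      has_stop <- nf >= 3 && substr(fpg, nf - 2, nf) %in% c("TAA", "TAG", "TGA")
      if (has_stop) nf <- nf - 3L
      if (substr(fpg, 1, 3) != "ATG") nf <- nf + 3L
    }
    extra <- 18L + nchar(params$linker) + nf
  }
  row$pop_in_len + row$pop_out_len + extra
}
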