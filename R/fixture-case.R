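# A complete ready-to-run synthetic test case: locus with one admissible
# planted cut site per region, a matching backbone, enzyme list, linker and
# tag gene. This is the unit the verification battery and the example
# directory writer are built from.

#' Build a complete synthetic design case
#'
#' Generates a locus with one planted linearization site in each of the 5'
#' flank (BamHI), the ORF (XhoI) and the 3' flank (EcoRI) at seeded-random
#' admissible distances, plus a backbone with a planted three-enzyme MCS, a
#' synthetic tag gene and the default linker. Every design task and both
#' pop-in/pop-out role assignments are designable on such a case.
#'
#' @param seed Integer seed; drives all random placement and backgrounds.
#' @param orf_len ORF length in bp (default 300).
#' @param flank_len Flank length in bp (default 1000).
#' @param min_homology Minimum homology used to place plants admissibly
#'   (default 70).
#' @return List with components `locus`, `backbone`, `params`, `spec`.
#' @export
make_fixture_case <- function(seed, orf_len = 300L, flank_len = 1000L,
                              min_homology = 70L) {
  enz <- suggested_enzymes()
  orf_len <- as.integer(orf_len)
  mh <- as.integer(min_homology)
  lo_fr <- mh + 10L
  hi_fr <- flank_len - mh - 10L
  lo_orf <- mh + 8L
  hi_orf <- orf_len - 3L - mh - 8L
  if (hi_orf <= lo_orf || hi_fr <= lo_fr) {
    stop("fixture case: regions too short for admissible plants at this ",
         "min_homology", call. = FALSE)
  }
  offs <- with_local_seed(seed, c(
    sample(lo_fr:hi_fr, 1L), sample(lo_orf:hi_orf, 1L), sample(lo_fr:hi_fr, 1L)))
  plants <- tibble::tibble(
    enzyme = c("BamHI", "XhoI", "EcoRI"),
    region = c("FR5", "ORF", "FR3"),
    offset = as.integer(offs))
  spec <- fixture_spec(seed, orf_len = orf_len, flank_len = flank_len,
                       plants = plants, forbidden = enz, enzymes = enz,
                       name = sprintf("SYN%04d", seed %% 10000L))
  locus <- make_goi(spec)
  bb <- make_backbone(seed + 10000L, enz, c("SacI", "KpnI", "SalI"))
  fpg <- make_fpg(seed + 20000L, enz)
  params <- design_params(enz, min_homology = mh, flank_len = flank_len,
                          fpg = fpg)
  list(locus = locus, backbone = bb, params = params, spec = spec)
}

#' Write a ready-to-run example input directory
#'
#' Materializes [make_fixture_case()] inputs as files: per-gene locus FASTAs,
#' backbone FASTA, enzyme list, linker and tag-gene FASTAs, and a key:value
#' config naming the MCS interval.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_genes Number of synthetic genes to write.
#' @return Invisibly, the directory path.
#' @export
write_example_inputs <- function(dir, seed = 1L, n_genes = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gene_dir <- file.path(dir, "genes")
  if (!dir.exists(gene_dir)) dir.create(gene_dir)
  case <- NULL
  for (i in seq_len(n_genes)) {
    case <- make_fixture_case(seed + i - 1L)
    write_fasta(stats::setNames(locus_seq(case$locus), case$locus$name),
                file.path(gene_dir, paste0(case$locus$name, ".fasta")))
  }
  write_fasta(stats::setNames(case$backbone$seq, case$backbone$name),
              file.path(dir, "backbone.fasta"), topology = "circular")
  file.copy(system.file("extdata", "enzymes_suggested.txt",
                        package = "pipodesign", mustWork = TRUE),
            file.path(dir, "enzymes.txt"), overwrite = TRUE)
  write_fasta(c(linker = case$params$linker), file.path(dir, "linker.fasta"))
  write_fasta(c(synthetic_fpg = case$params$fpg), file.path(dir, "fpg.fasta"))
  writeLines(c(sprintf("mcs_start: %d", case$backbone$mcs[1]),
               sprintf("mcs_end: %d", case$backbone$mcs[2]),
               "min_homology: 70", "r_homo: 2", "flank_len: 1000"),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Run the design/verification battery over seeded fixture cases
#'
#' For each seed: build a fixture case, design all three tasks, verify every
#' valid design by simulated pop-in/pop-out, and summarize.
#'
#' @param seeds Integer vector of case seeds.
#' @param tasks Tasks to run (default all three).
#' @param min_repeat Safety-scan threshold for [enumerate_pop_out()].
#' @return Tibble with one row per seed x task: design counts, coverage of
#'   both role assignments among valid candidates, and round-trip results.
#' @export
run_fixture_battery <- function(seeds, tasks = EDIT_TASKS, min_repeat = 25L) {
  rows <- list()
  for (seed in seeds) {
    case <- make_fixture_case(seed)
    for (task in tasks) {
      d <- pipo_design(case$locus, task, case$backbone, case$params)
      v <- verify_design(d, min_repeat = min_repeat)
      gl <- glance(d)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = seed, task = task,
        n_candidates = gl$n_candidates, n_valid = gl$n_valid,
        designable = gl$designable,
        both_assignments = length(unique(
          d$candidates$pop_in_region[d$candidates$status == "valid"])) >= 2L,
        optimal_insert_len = gl$optimal_insert_len,
        n_verified = nrow(v), n_roundtrip_ok = sum(v$ok),
        roundtrip_ok = nrow(v) > 0 && all(v$ok))
    }
  }
  dplyr::bind_rows(rows)
}
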