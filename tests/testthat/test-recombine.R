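# Pop-in/pop-out simulation: integration geometry, repeat annotation and
# excision-product classification.

test_that("intended edit has the expected structure per task", {
  case <- make_fixture_case(111)
  loc <- case$locus
  params <- case$params
  F <- loc$flank_len
  L <- nchar(loc$orf)

  del <- intended_edit(loc, "delete", params)
  expect_identical(nchar(del), 2L * F)
  expect_identical(del, paste0(loc$upstream, loc$downstream))

  tags <- c("NheI", "SpeI", "BglII")
  tc <- intended_edit(loc, "tag_c", params, tags)
  # tag gene appears exactly once
  expect_identical(
    length(gregexpr(params$fpg, tc, fixed = TRUE)[[1]]), 1L)
  # matches the independent string construction
  expect_identical(tc, paste0(loc$upstream, substr(loc$orf, 1, L - 3),
                              "GCTAGC", params$linker, "ACTAGT",
                              params$fpg, "TAA", "AGATCT", loc$downstream))

  tn <- intended_edit(loc, "tag_n", params, tags)
  expect_identical(tn, paste0(loc$upstream, "GCTAGC", "ATG",
                              substr(params$fpg, 4, nchar(params$fpg)),
                              "ACTAGT", params$linker, "AGATCT",
                              loc$orf, loc$downstream))
})

test_that("pop-in conserves length and duplicates the pop-in homology", {
  case <- make_fixture_case(121)
  d <- pipo_design(case$locus, "delete", case$backbone, case$params)
  cd <- d$candidates
  i <- which(cd$status == "valid")[1]
  plasmid <- cd$plasmid[[i]]
  lin <- linearize_plasmid(plasmid)
  integ <- simulate_pop_in(case$locus, lin, case$params$min_homology)

  wt_len <- nchar(paste0(case$locus$upstream, case$locus$orf,
                         case$locus$downstream))
  expect_identical(nchar(integ$seq), wt_len + nchar(lin$seq))

  # both copies of each repeat pair carry identical sequence
  for (r in seq_len(nrow(integ$repeats))) {
    rr <- integ$repeats[r, ]
    expect_identical(substr(integ$seq, rr$start1 + 1, rr$end1),
                     substr(integ$seq, rr$start2 + 1, rr$end2))
  }

  # the pop-in repeat contains the designed pop-in arm
  pin_arm_len <- cd$pop_in_len[[i]]
  rep1 <- integ$repeats[integ$repeats$label == "POP_IN_REPEAT", ]
  expect_gte(rep1$end1 - rep1$start1, pin_arm_len)

  # breaking one terminal base of homology fails the simulation
  broken <- lin
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
  broken$seq <- paste0(flip(substr(lin$seq, 1, 1)),
                       substr(lin$seq, 2, nchar(lin$seq)))
  expect_error(simulate_pop_in(case$locus, broken, case$params$min_homology),
               class = "pipo_homology_error")
})

test_that("pop-out yields exactly one reversion and one intended edit", {
  case <- make_fixture_case(131)
  for (task in c("delete", "tag_n", "tag_c")) {
    d <- pipo_design(case$locus, task, case$backbone, case$params)
    v <- verify_design(d)
    expect_gt(nrow(v), 0)
    expect_true(all(v$n_outcomes == 2L), info = task)
    expect_true(all(v$wt_ok & v$edit_ok), info = task)
    expect_true(all(v$n_other == 0L), info = task)
  }
})

test_that("deletion pop-out product contains no backbone or marker sequence", {
  case <- make_fixture_case(141)
  d <- pipo_design(case$locus, "delete", case$backbone, case$params)
  opt <- optimal_candidate(d)
  lin <- linearize_plasmid(opt$plasmid[[1]])
  integ <- simulate_pop_in(case$locus, lin, case$params$min_homology)
  outs <- enumerate_pop_out(integ, intended_edit(case$locus, "delete",
                                                 case$params))
  edit <- outs$product[outs$classification == "INTENDED_EDIT"]
  expect_identical(length(edit), 1L)
  marker <- substr(case$backbone$seq,
                   case$backbone$features$start[[1]] + 1,
                   case$backbone$features$end[[1]])
  expect_false(grepl(marker, edit, fixed = TRUE))
  expect_false(grepl(substr(case$backbone$seq, 1, 60), edit, fixed = TRUE))
})

test_that("classified outcome set is invariant under the role assignment", {
  # For deletions the two role assignments must leave byte-identical genomic
  # products. For tagging, the greedy tag-flank selection may assign different
  # 6 bp sites per assignment (the draft insert differs), so intended products
  # are compared after excising the three tag sites at their structural
  # positions in the edited locus.
  case <- make_fixture_case(151)
  F <- case$locus$flank_len
  L <- nchar(case$locus$orf)
  cut6 <- function(s, pos0) {   # drop 6 bases at 0-based position pos0
    paste0(substr(s, 1, pos0), substr(s, pos0 + 7, nchar(s)))
  }
  strip_sites <- function(product, task) {
    if (task == "delete") return(product)
    fpg <- case$params$fpg
    lk <- case$params$linker
    if (task == "tag_c") {
      p1 <- F + (L - 3L)
      s <- cut6(product, p1)
      s <- cut6(s, p1 + nchar(lk))
      cut6(s, p1 + nchar(lk) + nchar(fpg) + 3L)   # fpg carries appended stop
    } else {
      p1 <- F
      s <- cut6(product, p1)
      s <- cut6(s, p1 + nchar(fpg))               # fpg already starts with ATG
      cut6(s, p1 + nchar(fpg) + nchar(lk))
    }
  }
  for (task in c("delete", "tag_n", "tag_c")) {
    d <- pipo_design(case$locus, task, case$backbone, case$params)
    cd <- d$candidates
    valid <- which(cd$status == "valid")
    regions <- unique(cd$pop_in_region[valid])
    expect_gte(length(regions), 2L)   # both assignments produced designs
    products <- lapply(valid, function(i) {
      lin <- linearize_plasmid(cd$plasmid[[i]])
      tags <- if (!is.na(cd$tag_sites[[i]]) && nzchar(cd$tag_sites[[i]])) {
        strsplit(cd$tag_sites[[i]], ",")[[1]]
      } else NULL
      integ <- simulate_pop_in(case$locus, lin, case$params$min_homology)
      outs <- enumerate_pop_out(integ, intended_edit(case$locus, task,
                                                     case$params, tags))
      norm <- ifelse(outs$classification == "INTENDED_EDIT",
                     vapply(outs$product, strip_sites, character(1), task),
                     outs$product)
      sort(paste(outs$classification, norm))
    })
    # every valid candidate (either role assignment) yields the same set of
    # classified genomic products, up to the tag-site assignment
    for (j in seq_along(products)[-1]) {
      expect_identical(products[[j]], products[[1]], info = task)
    }
  }
})

test_that("length is conserved through each excision", {
  case <- make_fixture_case(161)
  d <- pipo_design(case$locus, "tag_c", case$backbone, case$params)
  opt <- optimal_candidate(d)
  lin <- linearize_plasmid(opt$plasmid[[1]])
  integ <- simulate_pop_in(case$locus, lin, case$params$min_homology)
  tags <- strsplit(opt$tag_sites[[1]], ",")[[1]]
  outs <- enumerate_pop_out(integ, intended_edit(case$locus, "tag_c",
                                                 case$params, tags))
  expect_true(all(nchar(outs$product) + outs$loop_len == nchar(integ$seq)))
})
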