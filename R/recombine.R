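# In-silico verification of designs: simulate the single-crossover pop-in
# integration of the linearized plasmid, annotate the two direct-repeat pairs
# it creates, and enumerate the pop-out excision products. Recombination is
# modeled as exact-match direct-repeat excision: no mismatch tolerance, no
# gene conversion, no outcome probabilities (the wet-lab efficiency of each
# outcome is an empirical quantity this module does not predict).

#' The intended edited locus
#'
#' The genomic sequence a correct pop-in/pop-out cycle should leave behind.
#'
#' @param locus A `gene_locus`.
#' @param task Edit task.
#' @param params A `pipo_params` object.
#' @param tag_sites For tagging tasks, the 3 assigned tag enzyme names.
#' @return DNA string of the edited locus.
#' @export
intended_edit <- function(locus, task, params, tag_sites = NULL) {
  task <- check_task(task)
  if (task == "delete") {
    return(paste0(locus$upstream, locus$downstream))
  }
  check_task_params(task, params)
  stopifnot(length(tag_sites) == 3L)
  tags <- params$tag_flank_enzymes
  s <- tags$recognition[match(tag_sites, tags$name)]
  if (task == "tag_c") {
    paste0(locus$upstream, orf_core(locus), s[[1]], params$linker, s[[2]],
           normalize_fpg(params$fpg, task), s[[3]], locus$downstream)
  } else {
    paste0(locus$upstream, s[[1]], normalize_fpg(params$fpg, task), s[[2]],
           params$linker, s[[3]], locus$orf, locus$downstream)
  }
}

# 0-based positions of all (overlapping) exact occurrences of `what` in `s`
find_exact <- function(s, what) {
  m <- gregexpr(paste0("(?=", what, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# length of the longest common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[[1]] - 1L
}

str_rev <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

# grow a direct-repeat pair to its maximal exact extent within the product
extend_repeat <- function(prod, s1, e1, s2, e2) {
  n <- nchar(prod)
  ch <- function(i) substr(prod, i + 1L, i + 1L)   # 0-based base accessor
  while (s1 > 0L && s2 > 0L && ch(s1 - 1L) == ch(s2 - 1L)) {
    s1 <- s1 - 1L; s2 <- s2 - 1L
  }
  while (e1 < s2 && e2 < n && ch(e1) == ch(e2)) {
    e1 <- e1 + 1L; e2 <- e2 + 1L
  }
  c(s1, e1, s2, e2)
}

#' Simulate pop-in integration by single crossover
#'
#' Locates the unique genomic position where the two terminal homologies of
#' the linearized plasmid map adjacently, and integrates the whole molecule
#' there. The result carries the two direct-repeat pairs that drive pop-out:
#' the pop-in region duplication (whose recombination reverts to wild type)
#' and the pop-out homology against its genomic counterpart (whose
#' recombination leaves the intended edit).
#'
#' @param wt_locus A `gene_locus` or plain DNA string (the wild-type locus).
#' @param linear_plasmid The linearized plasmid ([linearize_plasmid()]): an
#'   [annotated_seq] in genomic orientation whose ends carry at least
#'   `min_homology` bp of sequence identical to the genome around the cut.
#' @param min_homology Minimum terminal homology in bp.
#' @return A `pipo_integration`: list with `seq` (the locus after pop-in),
#'   `repeats` (tibble `label`, `start1`, `end1`, `start2`, `end2` in product
#'   coordinates), `insert_interval`, `backbone_interval`, and `wt`.
#' @export
simulate_pop_in <- function(wt_locus, linear_plasmid, min_homology) {
  wt <- if (inherits(wt_locus, "gene_locus")) locus_seq(wt_locus) else
    as_dna(wt_locus, "wild-type locus")
  stopifnot(inherits(linear_plasmid, "annotated_seq"),
            linear_plasmid$topology == "linear")
  P <- linear_plasmid$seq
  Lp <- nchar(P)
  mh <- as.integer(min_homology)
  if (Lp < 2L * mh) {
    rlang::abort("HOMOLOGY_NOT_FOUND: linearized plasmid shorter than twice the minimum homology",
                 class = "pipo_homology_error")
  }
  head_h <- substr(P, 1L, mh)
  tail_h <- substr(P, Lp - mh + 1L, Lp)

  cand <- find_exact(wt, head_h)
  cand <- cand[cand >= mh]
  cand <- cand[vapply(cand, function(p) subseq0(wt, p - mh, p) == tail_h, logical(1))]
  if (length(cand) != 1L) {
    rlang::abort(sprintf(
      "HOMOLOGY_NOT_FOUND: plasmid terminal homologies map to %d genomic position(s), need exactly 1",
      length(cand)), class = "pipo_homology_error")
  }
  p <- cand[[1]]
  n_wt <- nchar(wt)
  product <- paste0(subseq0(wt, 0L, p), P, subseq0(wt, p, n_wt))

  # maximal extension of the terminal homologies (the true pop-in repeat)
  b <- common_prefix_len(P, subseq0(wt, p, n_wt))
  a <- common_prefix_len(str_rev(P), str_rev(subseq0(wt, 0L, p)))
  repeats <- tibble::tibble(
    label = "POP_IN_REPEAT",
    start1 = p - a, end1 = p + b,
    start2 = p + Lp - a, end2 = p + Lp + b)

  pout <- get_feature(linear_plasmid, "POP_OUT_ARM")
  if (!is.null(pout)) {
    arm <- subseq0(P, pout$start, pout$end)
    g <- find_exact(wt, arm)
    g <- g[g + nchar(arm) <= p | g >= p]      # cleanly on one side of the cut
    if (length(g) >= 1L) {
      q <- g[[1]]
      ins_copy <- c(p + pout$start, p + pout$end)
      gen_copy <- if (q >= p) c(q + Lp, q + Lp + nchar(arm)) else c(q, q + nchar(arm))
      first <- if (gen_copy[1] < ins_copy[1]) gen_copy else ins_copy
      second <- if (gen_copy[1] < ins_copy[1]) ins_copy else gen_copy
      # extend to the maximal repeat so coincidental boundary matches are
      # part of the annotated pair (excision products are unchanged)
      ext <- extend_repeat(product, first[1], first[2], second[1], second[2])
      repeats <- dplyr::bind_rows(repeats, tibble::tibble(
        label = "POP_OUT_REPEAT",
        start1 = ext[1], end1 = ext[2],
        start2 = ext[3], end2 = ext[4]))
    }
  }

  bb <- get_feature(linear_plasmid, "BACKBONE")
  backbone_interval <- if (!is.null(bb)) c(p + bb$start, p + bb$end) else NULL

  structure(list(seq = product, repeats = repeats,
                 insert_interval = c(p, p + Lp),
                 backbone_interval = backbone_interval, wt = wt),
            class = "pipo_integration")
}

#' @export
print.pipo_integration <- function(x, ...) {
  cat(sprintf("<pipo_integration> %d bp (wild type %d bp + plasmid %d bp), %d repeat pair(s)\n",
              nchar(x$seq), nchar(x$wt), diff(x$insert_interval), nrow(x$repeats)))
  invisible(x)
}

#' Enumerate pop-out excision outcomes
#'
#' For each annotated direct-repeat pair, excises the loop between the two
#' copies (retaining one copy) and classifies the product by exact string
#' equality against the wild-type locus and the intended edit. A safety scan
#' additionally looks for any other direct repeats of at least `min_repeat` bp
#' flanking the integrated backbone block; such products are reported as
#' `OTHER`.
#'
#' @param integration A `pipo_integration` from [simulate_pop_in()].
#' @param intended The intended edited locus (string, see [intended_edit()]).
#' @param min_repeat Minimum repeat length for the safety scan (default 25 bp,
#'   below which spontaneous recombination is negligible).
#' @return Tibble with one row per outcome: `via` (repeat label), `product`
#'   (sequence), `loop_len`, `classification` in
#'   `{WT_REVERSION, INTENDED_EDIT, OTHER}`.
#' @export
enumerate_pop_out <- function(integration, intended, min_repeat = 25L) {
  stopifnot(inherits(integration, "pipo_integration"))
  prod <- integration$seq
  n <- nchar(prod)
  classify <- function(s) {
    if (identical(s, integration$wt)) "WT_REVERSION"
    else if (identical(s, intended)) "INTENDED_EDIT"
    else "OTHER"
  }
  excise <- function(s1, s2) paste0(subseq0(prod, 0L, s1), subseq0(prod, s2, n))

  rows <- lapply(seq_len(nrow(integration$repeats)), function(i) {
    r <- integration$repeats[i, ]
    out <- excise(r$start1, r$start2)
    tibble::tibble(via = r$label, product = out,
                   loop_len = r$start2 - r$start1,
                   classification = classify(out))
  })
  out <- dplyr::bind_rows(rows)

  extra <- scan_other_repeats(integration, min_repeat)
  if (nrow(extra) > 0) {
    more <- lapply(seq_len(nrow(extra)), function(i) {
      r <- extra[i, ]
      o <- excise(r$start1, r$start2)
      tibble::tibble(via = "OTHER_REPEAT", product = o,
                     loop_len = r$start2 - r$start1,
                     classification = classify(o))
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(more))
  }
  out
}

# Safety scan: shared k-mers between the region left of the integrated
# backbone block and the region right of it, excluding pairs that lie within
# an annotated repeat pair, merged into maximal repeats.
scan_other_repeats <- function(integration, k) {
  bb <- integration$backbone_interval
  if (is.null(bb)) return(tibble::tibble(start1 = integer(), end1 = integer(),
                                         start2 = integer(), end2 = integer()))
  prod <- integration$seq
  n <- nchar(prod)
  left_end <- bb[1]
  right_start <- bb[2]
  if (left_end < k || n - right_start < k) {
    return(tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer()))
  }
  lpos <- 0:(left_end - k)
  rpos <- right_start:(n - k)
  lk <- substring(prod, lpos + 1L, lpos + k)
  rk <- substring(prod, rpos + 1L, rpos + k)
  shared <- intersect(lk, rk)
  if (length(shared) == 0L) {
    return(tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer()))
  }
  reps <- integration$repeats
  keep_l <- lpos[lk %in% shared]
  keep_lk <- lk[lk %in% shared]
  keep_r <- rpos[rk %in% shared]
  keep_rk <- rk[rk %in% shared]
  r_by_kmer <- split(keep_r, keep_rk)
  rs_list <- r_by_kmer[keep_lk]
  reps_n <- lengths(rs_list)
  if (sum(reps_n) > 200000) {                 # degenerate input guard
    rs_list <- rs_list[seq_len(min(length(rs_list), 5000L))]
    keep_l <- keep_l[seq_len(length(rs_list))]
    reps_n <- lengths(rs_list)
  }
  lv <- rep(keep_l, reps_n)
  rv <- unlist(rs_list, use.names = FALSE)
  annotated <- rep(FALSE, length(lv))
  for (i in seq_len(nrow(reps))) {
    annotated <- annotated |
      (lv >= reps$start1[[i]] & lv + k <= reps$end1[[i]] &
       rv >= reps$start2[[i]] & rv + k <= reps$end2[[i]] &
       (rv - lv) == (reps$start2[[i]] - reps$start1[[i]]))
  }
  lv <- lv[!annotated]
  rv <- rv[!annotated]
  if (length(lv) == 0L) {
    return(tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer()))
  }
  m <- cbind(lv, rv)
  # merge k-mer pairs with the same offset into maximal repeats
  off <- m[, 2] - m[, 1]
  outs <- list()
  for (o in unique(off)) {
    ls <- sort(m[off == o, 1])
    brk <- c(0L, which(diff(ls) > 1L), length(ls))
    for (i in seq_len(length(brk) - 1L)) {
      seg <- ls[(brk[i] + 1L):brk[i + 1L]]
      outs[[length(outs) + 1L]] <- tibble::tibble(
        start1 = seg[[1]], end1 = seg[[length(seg)]] + k,
        start2 = seg[[1]] + o, end2 = seg[[length(seg)]] + o + k)
    }
  }
  dplyr::bind_rows(outs)
}

#' Verify every valid design by simulated pop-in/pop-out
#'
#' The round-trip guarantee this package is built around: for each valid
#' candidate, linearize the plasmid, integrate it, enumerate the pop-out
#' products, and check that they are exactly one wild-type reversion equal to
#' the input locus and one intended edit, with no other products.
#'
#' @param design A `pipo_design`.
#' @param min_repeat Safety-scan repeat threshold (see [enumerate_pop_out()]).
#' @return Tibble with one row per valid candidate: `enzyme`,
#'   `pop_in_region`, `n_outcomes`, `wt_ok`, `edit_ok`, `n_other`, `ok`.
#' @export
verify_design <- function(design, min_repeat = 25L) {
  stopifnot(inherits(design, "pipo_design"))
  cd <- design$candidates
  valid <- which(cd$status == "valid")
  rows <- lapply(valid, function(i) {
    plasmid <- cd$plasmid[[i]]
    lin <- linearize_plasmid(plasmid)
    tag_sites <- if (!is.na(cd$tag_sites[[i]]) && nzchar(cd$tag_sites[[i]])) {
      strsplit(cd$tag_sites[[i]], ",", fixed = TRUE)[[1]]
    } else NULL
    edited <- intended_edit(design$locus, design$task, design$params, tag_sites)
    integ <- simulate_pop_in(design$locus, lin, design$params$min_homology)
    outs <- enumerate_pop_out(integ, edited, min_repeat)
    wt_ok <- sum(outs$classification == "WT_REVERSION") == 1L
    edit_ok <- sum(outs$classification == "INTENDED_EDIT") == 1L
    n_other <- sum(outs$classification == "OTHER")
    tibble::tibble(enzyme = cd$enzyme[[i]],
                   pop_in_region = cd$pop_in_region[[i]],
                   n_outcomes = nrow(outs), wt_ok = wt_ok, edit_ok = edit_ok,
                   n_other = n_other,
                   ok = wt_ok && edit_ok && n_other == 0L && nrow(outs) == 2L)
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(enzyme = character(), pop_in_region = character(),
                          n_outcomes = integer(), wt_ok = logical(),
                          edit_ok = logical(), n_other = integer(),
                          ok = logical()))
  }
  dplyr::bind_rows(rows)
}
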