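# The full design engine: run every candidate linearization cut site through
# arm sizing, tag-site selection, insert assembly, subcloning-pair selection
# and plasmid assembly; flag the optimal (minimal-synthesis) design.

#' Design PIPO plasmids for a gene locus and edit task
#'
#' Runs the complete pipeline for every candidate linearization cut site in
#' both role assignments and returns all candidates, valid and rejected, with
#' machine-readable rejection reasons. Among valid candidates exactly one is
#' flagged optimal: minimal insert length, ties broken by larger achieved
#' pop-out/pop-in ratio, then smaller junction distance, then enzyme file
#' order.
#'
#' @param locus A `gene_locus` (see [parse_goi()]).
#' @param task One of `"delete"`, `"tag_n"`, `"tag_c"`.
#' @param bb A [backbone()] object (or pass `mcs` with a plain sequence).
#' @param params A `pipo_params` object (see [design_params()]).
#' @param mcs Optional MCS interval when `bb` is a plain sequence string.
#' @return An object of class `pipo_design`; see [tidy.pipo_design()] and
#'   [glance.pipo_design()]. The `candidates` tibble carries list-columns
#'   `insert` and `plasmid` holding the annotated molecules of valid
#'   candidates.
#' @export
pipo_design <- function(locus, task, bb, params, mcs = NULL) {
  task <- check_task(task)
  stopifnot(inherits(locus, "gene_locus"), inherits(params, "pipo_params"))
  if (!inherits(bb, "pipo_backbone")) bb <- backbone(bb, mcs)
  check_task_params(task, params)
  tagging <- task %in% c("tag_n", "tag_c")
  slots <- if (tagging) tag_slot_specs(locus, task, params) else NULL

  # backbone scans are candidate-independent: do them once
  bb_hits <- find_sites(bb$seq, params$enzymes, "circular")
  bb_tag_counts <- if (tagging) {
    counts <- vapply(params$tag_flank_enzymes$recognition,
                     function(r) count_one(bb$seq, r, "circular"), integer(1))
    stats::setNames(counts, params$tag_flank_enzymes$name)
  } else NULL

  cands <- enumerate_candidates(locus, task, params)
  n <- nrow(cands)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- as.list(cands[i, ])
    row <- c(cand, list(
      pop_in_len = NA_integer_, pop_out_len = NA_integer_,
      achieved_ratio = NA_real_, truncated = NA,
      tag_sites = NA_character_, mcs_left = NA_character_,
      mcs_right = NA_character_, insert_len = NA_integer_,
      status = "rejected", warnings = "", insert = list(NULL),
      plasmid = list(NULL)))

    if (!cand$admissible) { res[[i]] <- row; next }

    arms <- build_arms(locus, task, cand, params)
    row$pop_in_len <- arms$pop_in_len
    row$pop_out_len <- arms$pop_out_len
    row$achieved_ratio <- arms$achieved_ratio
    row$truncated <- arms$truncated
    row$warnings <- paste(arms$warnings, collapse = ",")

    tag_sites <- character(0)
    insert <- NULL
    if (tagging) {
      draft <- c(arms$pop_in, arms$pop_out, params$linker,
                 normalize_fpg(params$fpg, task))
      # retry loop: a concatenation junction in the assembled insert can
      # coincidentally recreate an assigned site; exclude the offender and
      # reselect rather than rejecting the cut outright
      excluded <- character(0)
      repeat {
        tag_sites <- select_tag_flank_enzymes(draft, bb$seq, params,
                                              cand$enzyme, slots,
                                              bb_counts = bb_tag_counts,
                                              exclude = excluded)
        if (is.null(tag_sites)) break
        insert <- assemble_insert(locus, task, arms, cand, params, tag_sites)
        tag_rows <- params$tag_flank_enzymes[
          match(tag_sites, params$tag_flank_enzymes$name), , drop = FALSE]
        dup <- tag_sites[vapply(tag_rows$recognition, function(r)
          count_one(insert$seq, r, "linear") != 1L, logical(1))]
        if (length(dup) == 0L) break
        excluded <- c(excluded, dup)
        insert <- NULL
      }
      if (is.null(tag_sites) || is.null(insert)) {
        row$reason <- "TAG_SITES_UNAVAILABLE"
        res[[i]] <- row
        next
      }
      row$tag_sites <- paste(tag_sites, collapse = ",")
    } else {
      insert <- assemble_insert(locus, task, arms, cand, params, NULL)
    }
    # a junction can likewise duplicate the linearization site in the insert
    lin_recog <- params$enzymes$recognition[params$enzymes$name == cand$enzyme]
    if (count_one(insert$seq, lin_recog, "linear") != 1L) {
      row$reason <- "LINEARIZATION_NOT_UNIQUE"
      res[[i]] <- row
      next
    }
    row$insert_len <- nchar(insert$seq)
    row$insert <- list(insert)

    sel <- select_mcs_enzymes(insert, bb, params, cand$enzyme, tag_sites,
                              bb_hits = bb_hits)
    if (!is.null(sel$reason)) {
      row$reason <- sel$reason
      row$insert_len <- NA_integer_    # rejected: nothing to synthesize
      res[[i]] <- row
      next
    }
    row$mcs_left <- sel$left
    row$mcs_right <- sel$right
    row$plasmid <- list(sel$plasmid)
    row$status <- "valid"
    row$reason <- NA_character_
    res[[i]] <- row
  }

  candidates <- if (n > 0) {
    dplyr::bind_rows(lapply(res, tibble::as_tibble))
  } else {
    empty_candidate_table()
  }
  candidates$optimal <- rep(FALSE, nrow(candidates))
  valid <- which(candidates$status == "valid")
  if (length(valid) > 0) {
    v <- candidates[valid, ]
    ord <- order(v$insert_len, -v$achieved_ratio, v$d_junction, seq_along(valid))
    candidates$optimal[valid[ord[[1]]]] <- TRUE
  }

  structure(list(candidates = candidates, locus = locus, task = task,
                 params = params, backbone = bb),
            class = "pipo_design")
}

empty_candidate_table <- function() {
  tibble::tibble(
    pop_in_region = character(), pop_out_region = character(),
    enzyme = character(), strand = character(), site_start = integer(),
    cut_pos = integer(), d_junction = integer(), d_distal = integer(),
    admissible = logical(), reason = character(), pop_in_len = integer(),
    pop_out_len = integer(), achieved_ratio = double(), truncated = logical(),
    tag_sites = character(), mcs_left = character(), mcs_right = character(),
    insert_len = integer(), status = character(), warnings = character(),
    insert = list(), plasmid = list())
}

#' @export
print.pipo_design <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pipo_design> %s / %s: %d candidate(s), %d valid\n",
              g$gene, g$task, g$n_candidates, g$n_valid))
  if (g$n_valid > 0) {
    cat(sprintf("  optimal: %s in %s, insert %d bp (ratio %.2f%s)\n",
                g$optimal_enzyme, g$optimal_region, g$optimal_insert_len,
                g$optimal_ratio, if (isTRUE(g$optimal_truncated)) ", pop-out truncated" else ""))
  } else {
    tab <- table(x$candidates$reason)
    if (length(tab) > 0) {
      cat("  no valid design; rejection reasons: ",
          paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    } else {
      cat("  no candidate cut sites found\n")
    }
  }
  invisible(x)
}

#' Tidy a design result into one row per candidate
#'
#' @param x A `pipo_design`.
#' @param ... Unused.
#' @return Tibble with one row per candidate cut site (sequence list-columns
#'   dropped), including status, rejection reason and the `optimal` flag.
#' @export
tidy.pipo_design <- function(x, ...) {
  out <- x$candidates
  out$gene <- x$locus$name
  out$task <- x$task
  dplyr::select(out, "gene", "task", "enzyme", "pop_in_region",
                "pop_out_region", "strand", "site_start", "cut_pos",
                "d_junction", "d_distal", "pop_in_len", "pop_out_len",
                "achieved_ratio", "truncated", "tag_sites", "mcs_left",
                "mcs_right", "insert_len", "status", "reason", "warnings",
                "optimal")
}

#' One-row summary of a design run
#'
#' @param x A `pipo_design`.
#' @param ... Unused.
#' @return One-row tibble: candidate counts, validity, and the optimal
#'   design's enzyme, region, insert length, achieved ratio and truncation.
#' @export
glance.pipo_design <- function(x, ...) {
  cd <- x$candidates
  opt <- cd[which(cd$optimal), , drop = FALSE]
  tibble::tibble(
    gene = x$locus$name, task = x$task,
    n_candidates = nrow(cd),
    n_admissible = sum(cd$admissible),
    n_valid = sum(cd$status == "valid"),
    designable = sum(cd$status == "valid") > 0,
    optimal_enzyme = if (nrow(opt)) opt$enzyme[[1]] else NA_character_,
    optimal_region = if (nrow(opt)) opt$pop_in_region[[1]] else NA_character_,
    optimal_insert_len = if (nrow(opt)) opt$insert_len[[1]] else NA_integer_,
    optimal_ratio = if (nrow(opt)) opt$achieved_ratio[[1]] else NA_real_,
    optimal_truncated = if (nrow(opt)) opt$truncated[[1]] else NA)
}

#' Extract the optimal candidate row (with molecules) from a design
#'
#' @param x A `pipo_design`.
#' @return One-row tibble including the `insert` and `plasmid` list-columns,
#'   or a zero-row tibble when no valid design exists.
#' @export
optimal_candidate <- function(x) {
  stopifnot(inherits(x, "pipo_design"))
  x$candidates[which(x$candidates$optimal), , drop = FALSE]
}

#' Plot candidate insert lengths along the locus
#'
#' One point per enumerated candidate at its cut position in locus
#' coordinates; valid candidates show their insert length, rejected ones are
#' drawn at the baseline, and the optimal design is highlighted.
#'
#' @param object A `pipo_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pipo_design <- function(object, ...) {
  cd <- tidy(object)
  F <- object$locus$flank_len
  L <- nchar(object$locus$orf)
  off <- c(FR5 = 0L, ORF = F, FR3 = F + L)
  cd$locus_pos <- cd$cut_pos + off[cd$pop_in_region]
  cd$insert_len_plot <- ifelse(is.na(cd$insert_len), 0L, cd$insert_len)
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$locus_pos,
                                   y = .data$insert_len_plot,
                                   colour = .data$status,
                                   shape = .data$pop_in_region)) +
    ggplot2::annotate("rect", xmin = F, xmax = F + L, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = cd[cd$optimal, , drop = FALSE],
                        shape = 21, size = 4, stroke = 1.2,
                        colour = "black", fill = NA) +
    ggplot2::labs(x = "cut position (locus coordinate, bp)",
                  y = "insert length (bp; rejected drawn at 0)",
                  colour = "status", shape = "cut region",
                  title = sprintf("%s / %s: candidate linearization cut sites",
                                  object$locus$name, object$task),
                  subtitle = "shaded band = ORF; circled point = optimal design")
}
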