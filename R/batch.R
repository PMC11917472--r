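# Genome-wide batch driver: one design per gene x task, aggregated into a
# designability summary (the per-genome statistic the tool reports when run
# over every ORF of a genome).

#' Batch design over many genes and tasks
#'
#' @param genes Either a directory containing one FASTA per gene named
#'   `<GENE>.fasta`, or a (named) list of `gene_locus` objects. Malformed
#'   files are skipped with a warning and counted as failures, not crashes.
#' @param tasks Character vector of tasks to design for each gene.
#' @param bb A [backbone()] object.
#' @param params A `pipo_params` object.
#' @return A tibble of class `pipo_batch`, one row per gene x task: `gene`,
#'   `task`, `n_candidates`, `n_valid`, `optimal_insert_len`,
#'   `optimal_enzyme`, `status` (`designable` / `undesignable` / `error`),
#'   `reasons` (tallied rejection reasons).
#' @export
batch_design <- function(genes, tasks = EDIT_TASKS, bb, params) {
  tasks <- vapply(tasks, check_task, character(1), USE.NAMES = FALSE)
  loci <- if (is.character(genes) && length(genes) == 1L && dir.exists(genes)) {
    files <- sort(list.files(genes, pattern = "\\.fasta$", full.names = TRUE))
    stats::setNames(lapply(files, function(f) {
      tryCatch(read_goi(f, params$flank_len),
               error = function(e) {
                 warning("skipping ", basename(f), ": ", conditionMessage(e),
                         call. = FALSE)
                 structure(list(msg = conditionMessage(e)), class = "pipo_bad_locus")
               })
    }), sub("\\.fasta$", "", basename(files)))
  } else {
    genes
  }

  rows <- list()
  for (g in seq_along(loci)) {
    locus <- loci[[g]]
    gene <- if (!is.null(names(loci))) names(loci)[[g]] else
      if (inherits(locus, "gene_locus")) locus$name else paste0("gene", g)
    for (task in tasks) {
      row <- tryCatch({
        if (inherits(locus, "pipo_bad_locus")) stop(locus$msg, call. = FALSE)
        d <- pipo_design(locus, task, bb, params)
        gl <- glance(d)
        reasons <- table(d$candidates$reason)
        tibble::tibble(
          gene = gene, task = task,
          n_candidates = gl$n_candidates, n_valid = gl$n_valid,
          optimal_insert_len = gl$optimal_insert_len,
          optimal_enzyme = gl$optimal_enzyme,
          status = if (gl$n_valid > 0) "designable" else "undesignable",
          reasons = paste(sprintf("%s:%d", names(reasons), as.integer(reasons)),
                          collapse = ","))
      }, error = function(e) {
        tibble::tibble(gene = gene, task = task, n_candidates = NA_integer_,
                       n_valid = 0L, optimal_insert_len = NA_integer_,
                       optimal_enzyme = NA_character_, status = "error",
                       reasons = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pipo_batch", class(out))
  out
}

#' Aggregate summary of a batch run
#'
#' @param x A `pipo_batch` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of gene x task rows, number designable,
#'   the designable fraction, and insert-length quartiles over designable
#'   rows.
#' @export
glance.pipo_batch <- function(x, ...) {
  ok <- x$n_valid >= 1L
  q <- stats::quantile(x$optimal_insert_len[ok], c(0.25, 0.5, 0.75),
                       na.rm = TRUE, names = FALSE)
  tibble::tibble(
    n_tasks = nrow(x),
    n_designable = sum(ok),
    designable_fraction = sum(ok) / nrow(x),
    insert_len_q1 = q[[1]], insert_len_median = q[[2]], insert_len_q3 = q[[3]])
}
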