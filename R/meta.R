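# Meta-experiment assembly: link studies that share biology, filter unlinked
# ones, and merge the retained studies over their common gene set.

#' Link experiments through a shared biological covariate
#'
#' Builds a graph with one node per experiment and an edge whenever two
#' experiments share at least one category of `bio_covariate`. Experiments
#' outside the largest connected component are filtered out (component ties are
#' broken by larger total sample count, then by lexicographically smallest
#' member id). Experiments lacking the covariate are unlinked by definition.
#'
#' @param experiments list of [experiment()] objects (>= 2).
#' @param bio_covariate name of the metadata column used for linking.
#' @param log optional internal log collector.
#' @return list with `retained` (experiments, id order), `discarded`
#'   (data.frame of id/reason) and `edges` (data.frame of linked id pairs).
#' @export
link_experiments <- function(experiments, bio_covariate, log = NULL) {
  if (length(experiments) < 2) stop("need at least 2 experiments")
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("experiment ids must be unique")
  names(experiments) <- ids

  cats <- lapply(experiments, function(e) {
    if (!bio_covariate %in% colnames(e$sample_meta)) return(character(0))
    unique(as.character(e$sample_meta[[bio_covariate]]))
  })

  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(cats[[i]], cats[[j]])))
      adj[i, j] <- adj[j, i] <- TRUE
  }

  # connected components by breadth-first search
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }

  sizes <- tabulate(comp)
  samp_tot <- vapply(seq_len(max(comp)), function(cc)
    sum(vapply(experiments[comp == cc], function(e) ncol(e$matrix), numeric(1))),
    numeric(1))
  first_id <- vapply(seq_len(max(comp)), function(cc) min(ids[comp == cc]), character(1))
  ord <- order(-sizes, -samp_tot, first_id)
  best <- ord[1]

  retained_ids <- sort(ids[comp == best])
  if (length(retained_ids) < 2) stop("no linkable experiments")

  discarded <- data.frame(id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (ids[i] %in% retained_ids) next
    reason <- if (!length(cats[[i]])) paste0("covariate '", bio_covariate, "' missing")
              else if (sizes[comp[i]] == 1) "unlinked (no shared category)"
              else "outside largest linked component"
    discarded <- rbind(discarded, data.frame(id = ids[i], reason = reason,
                                             stringsAsFactors = FALSE))
    log_line(log, "link_experiments: discarded ", ids[i], " (", reason, ")")
  }

  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      stringsAsFactors = FALSE)
  list(retained = experiments[retained_ids], discarded = discarded, edges = edges)
}

#' Merge linked experiments into a meta-experiment
#'
#' Rows are restricted to the intersection of the member gene sets (sorted
#' lexicographically); columns are concatenated in experiment-id order. Each
#' sample's batch is its source experiment id and its biological label is its
#' `bio_covariate` category. Sample ids duplicated across experiments are
#' disambiguated by prefixing the experiment id.
#'
#' @param experiments list of retained [experiment()] objects sharing one
#'   technology.
#' @inheritParams link_experiments
#' @return an object of class `meta_experiment` with elements `matrix`,
#'   `batch`, `bio`, `technology` and `genes_lost_frac`.
#' @export
merge_experiments <- function(experiments, bio_covariate, log = NULL) {
  if (length(experiments) < 2) stop("need at least 2 experiments to merge")
  ids <- vapply(experiments, function(e) e$id, character(1))
  experiments <- experiments[order(ids)]
  ids <- sort(ids)

  tech <- unique(vapply(experiments, function(e) e$technology, character(1)))
  if (length(tech) > 1) stop("mixed technologies: ", paste(tech, collapse = ", "))
  for (e in experiments)
    if (!bio_covariate %in% colnames(e$sample_meta))
      stop("experiment ", e$id, " lacks covariate '", bio_covariate, "'")

  gene_sets <- lapply(experiments, function(e) rownames(e$matrix))
  genes <- Reduce(intersect, gene_sets)
  if (!length(genes)) stop("empty intersection of gene sets")
  genes <- sort(genes)
  total <- length(unique(unlist(gene_sets)))
  lost_frac <- 1 - length(genes) / total
  log_line(log, "merge_experiments: ", length(genes), " shared genes; ",
           sprintf("%.1f%%", 100 * lost_frac), " of the union lost")

  all_samples <- unlist(lapply(experiments, function(e) colnames(e$matrix)))
  prefix <- anyDuplicated(all_samples) > 0

  mats <- list(); batch <- character(0); bio <- character(0)
  for (e in experiments) {
    m <- e$matrix[genes, , drop = FALSE]
    if (prefix) colnames(m) <- paste(e$id, colnames(m), sep = ".")
    mats[[e$id]] <- m
    batch <- c(batch, rep(e$id, ncol(m)))
    bio <- c(bio, as.character(e$sample_meta[[bio_covariate]]))
  }
  mat <- do.call(cbind, mats)
  names(batch) <- colnames(mat)
  names(bio) <- colnames(mat)

  meta <- structure(
    list(matrix = mat, batch = batch, bio = bio, technology = tech,
         bio_covariate = bio_covariate, genes_lost_frac = lost_frac),
    class = "meta_experiment"
  )
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  b <- table(meta$batch)
  if (length(b) < 2) stop("meta-experiment needs >= 2 batches")
  if (any(b < 2)) stop("every batch must contribute >= 2 samples")
  if (nrow(meta$matrix) < 1) stop("meta-experiment has no genes")
  invisible(meta)
}

#' @export
print.meta_experiment <- function(x, ...) {
  b <- table(x$batch)
  cat("<meta_experiment> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", x$technology, ")\n", sep = "")
  cat("  batches: ", paste(sprintf("%s (%d)", names(b), b), collapse = ", "), "\n", sep = "")
  cat("  biology [", x$bio_covariate, "]: ",
      paste(names(table(x$bio)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Extract matrix/batch/bio from a meta_experiment or a plain list with the
# same fields (the plain form is handy for small edge-case inputs).
meta_parts <- function(meta) {
  if (inherits(meta, "meta_experiment")) validate_meta(meta)
  if (is.matrix(meta)) stop("expected a meta_experiment, got a bare matrix")
  list(matrix = meta$matrix,
       batch = as.character(meta$batch),
       bio = if (is.null(meta$bio)) NULL else as.character(meta$bio))
}

#' Serialize / load a meta-experiment bundle
#'
#' A bundle is a directory holding `matrix.tsv` (gene-by-sample values),
#' `samples.tsv` (sample_id, batch, bio) and `manifest.json` (technology and
#' dimensions).
#'
#' @param meta a `meta_experiment`.
#' @param dir bundle directory (created if missing).
#' @return `write_meta` returns `dir` invisibly; `read_meta` a `meta_experiment`.
#' @export
write_meta <- function(meta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(meta$matrix, file.path(dir, "matrix.tsv"))
  samples <- data.frame(sample_id = colnames(meta$matrix),
                        batch = unname(meta$batch),
                        bio = unname(meta$bio), stringsAsFactors = FALSE)
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(technology = meta$technology,
                   bio_covariate = meta$bio_covariate %||% "bio",
                   n_genes = nrow(meta$matrix), n_samples = ncol(meta$matrix))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_meta
#' @export
read_meta <- function(dir) {
  mat <- read_tsv_matrix(file.path(dir, "matrix.tsv"))
  samples <- utils::read.delim(file.path(dir, "samples.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(samples$sample_id, colnames(mat)))
    stop("samples.tsv does not match matrix columns")
  if (identical(manifest$technology, "rnaseq")) mat <- round(mat)
  batch <- stats::setNames(samples$batch, samples$sample_id)
  bio <- stats::setNames(samples$bio, samples$sample_id)
  meta <- structure(
    list(matrix = mat, batch = batch, bio = bio,
         technology = manifest$technology,
         bio_covariate = manifest$bio_covariate, genes_lost_frac = NA_real_),
    class = "meta_experiment"
  )
  validate_meta(meta)
  meta
}

# Split the (uncorrected) meta-experiment back into per-batch matrices on the
# shared gene space; used by the HVG-conservation metric.
split_by_batch <- function(mat, batch) {
  lapply(split(seq_along(batch), batch), function(idx) mat[, idx, drop = FALSE])
}
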