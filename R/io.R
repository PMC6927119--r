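#' Read a delimited edge-list table
#'
#' Shared reader for all inputs: tab- or whitespace-delimited text, optional
#' header, comment lines starting with \code{#}. Malformed lines (fewer
#' columns than required) raise an error naming the line number.
#'
#' @param path file path.
#' @param ncol required minimum column count.
#' @param header does the file carry a header line (default autodetect: a
#'   first non-comment line whose last required column is non-numeric when a
#'   numeric column is expected).
#' @param numeric_cols indices of columns that must parse as numbers.
#' @return data frame of the first \code{ncol} columns, as character except
#'   \code{numeric_cols}.
#' @export
read_edge_list <- function(path, ncol = 2, header = FALSE,
                           numeric_cols = integer(0)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data lines in ", path)
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) < ncol)
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": expected at least ", ncol, " fields")
  if (header) { fields <- fields[-1]; lineno <- lineno[-1] }
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(ncol))),
                      stringsAsFactors = FALSE)
  for (j in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v))
      stop("non-numeric value in column ", j, ", line ",
           lineno[which(is.na(v))[1]], " of ", path)
    df[[j]] <- v
  }
  df
}

#' Read all pipeline inputs and reconcile their label universes
#'
#' Loads the four input tables (ontology child--parent edges, one or more
#' annotation corpora, the weighted gene network, miRNA target sets, and the
#' known interactions) and restricts the interaction matrix to miRNAs with
#' computable functional similarity and diseases present in the ontology.
#' Dropped rows are counted in the returned reconciliation report.
#'
#' @param ontology path to the child--parent table.
#' @param corpora character vector of corpus paths (disease_id, object_id).
#' @param network path to the gene network table (gene_a, gene_b, score).
#' @param targets path to the miRNA target table (mirna_id, gene_id).
#' @param interactions path to the known-interaction table
#'   (mirna_id, disease_id).
#' @return list with \code{dag}, \code{corpora}, \code{network},
#'   \code{targets}, \code{x} (binary interaction matrix over the reconciled
#'   universe) and \code{report} (dropped-row counts).
#' @export
read_knmbp_data <- function(ontology, corpora, network, targets,
                            interactions) {
  dag <- disease_dag(read_edge_list(ontology, 2))
  corp <- lapply(seq_along(corpora), function(i)
    corpus_annotation(read_edge_list(corpora[i], 2),
                      corpus_id = basename(corpora[i])))
  net <- gene_network(read_edge_list(network, 3, numeric_cols = 3))
  tg <- read_edge_list(targets, 2)
  tsets <- split(tg[[2]], tg[[1]])
  it <- read_edge_list(interactions, 2)

  mirnas <- sort(names(tsets))
  diseases <- intersect(dag$terms, unique(it[[2]]))
  keep <- it[[1]] %in% mirnas & it[[2]] %in% diseases
  dropped <- sum(!keep)
  it <- unique(it[keep, , drop = FALSE])
  if (!nrow(it))
    stop("empty intersection: no interaction links both a known miRNA (",
         length(mirnas), ") and an ontology disease (", length(diseases), ")")
  x <- matrix(0, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  x[cbind(match(it[[1]], mirnas), match(it[[2]], diseases))] <- 1
  list(dag = dag, corpora = corp, network = net, targets = tsets, x = x,
       report = list(interactions_kept = nrow(it),
                     interactions_dropped = dropped,
                     n_mirnas = length(mirnas), n_diseases = length(diseases)))
}

#' Write a matrix as delimited text with a provenance header
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param meta named list recorded in \code{# key: value} header lines.
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(as.data.frame(m), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write a long score table (mirna_id, disease_id, score)
#'
#' @param scores score matrix with dimnames.
#' @param path output path.
#' @param meta header metadata, see \code{\link{write_matrix_tsv}}.
#' @export
write_score_table <- function(scores, path, meta = list()) {
  df <- data.frame(mirna_id = rep(rownames(scores), ncol(scores)),
                   disease_id = rep(colnames(scores), each = nrow(scores)),
                   score = as.vector(scores))
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated bundle as the delimited-text input formats
#'
#' Round-trips the synthetic generator through the same file formats the
#' readers consume: ontology edges, per-corpus annotation records, gene
#' network scores, target pairs and interaction pairs.
#'
#' @param dat bundle from \code{\link{simulate_knmbp_data}}.
#' @param dir output directory (created if missing).
#' @return named list of the paths written (\code{corpora} holds one path per
#'   corpus).
#' @export
write_knmbp_data <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(dat$ontology$edges, p("ontology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  corp_paths <- vapply(seq_along(dat$ontology$corpora), function(i) {
    ann <- dat$ontology$corpora[[i]]
    counts <- ann$counts[ann$counts > 0]
    df <- data.frame(disease = rep(names(counts), counts),
                     object = sprintf("O%05d", seq_len(sum(counts))))
    f <- p(sprintf("corpus%d.tsv", i))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    f
  }, character(1))
  utils::write.table(dat$gene_side$edges, p("gene_network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tg <- data.frame(mirna = rep(names(dat$gene_side$targets),
                               lengths(dat$gene_side$targets)),
                   gene = unlist(dat$gene_side$targets, use.names = FALSE))
  utils::write.table(tg, p("targets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  idx <- which(dat$x == 1)
  it <- data.frame(mirna = rownames(dat$x)[row(dat$x)[idx]],
                   disease = colnames(dat$x)[col(dat$x)[idx]])
  utils::write.table(it, p("interactions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(ontology = p("ontology.tsv"), corpora = corp_paths,
       network = p("gene_network.tsv"), targets = p("targets.tsv"),
       interactions = p("interactions.tsv"))
}
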