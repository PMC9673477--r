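#' Genotype matrix container
#'
#' A `gs_genotypes` object holds a samples-by-markers matrix of additive
#' minor-allele counts (0/1/2) together with unique sample and marker
#' identifiers and, optionally, per-marker chromosome/position metadata.
#' All entries must be present (the pipeline assumes a fully imputed panel).
#'
#' @param values integer matrix, rows = samples, columns = markers, values
#'   in \{0, 1, 2\}.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to rownames(values) or `S1..Sn`.
#' @param marker_ids character vector of unique marker identifiers; defaults
#'   to colnames(values) or `M1..Mm`.
#' @param chromosome optional per-marker positive integer vector.
#' @param position optional per-marker 1-based position vector.
#' @return A `gs_genotypes` object.
#' @export
gs_genotypes <- function(values, sample_ids = NULL, marker_ids = NULL,
                         chromosome = NULL, position = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values); m <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(values)
    if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(m))
  }
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  if (length(marker_ids) != m)
    stop("length(marker_ids) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id: ",
         marker_ids[duplicated(marker_ids)][1], call. = FALSE)
  if (anyNA(values))
    stop("genotype matrix contains missing values; the pipeline expects a fully imputed panel",
         call. = FALSE)
  bad <- which(!(values %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% n) + 1L
    j <- ((bad[1] - 1L) %/% n) + 1L
    stop(sprintf("genotype value %s at sample '%s', marker '%s' is not in {0,1,2}",
                 values[bad[1]], sample_ids[i], marker_ids[j]), call. = FALSE)
  }
  if (!is.null(chromosome) && length(chromosome) != m)
    stop("chromosome must have one entry per marker", call. = FALSE)
  if (!is.null(position) && length(position) != m)
    stop("position must have one entry per marker", call. = FALSE)
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(
    list(values = values, sample_ids = sample_ids, marker_ids = marker_ids,
         chromosome = chromosome, position = position),
    class = "gs_genotypes")
}

#' @export
print.gs_genotypes <- function(x, ...) {
  cat(sprintf("<gs_genotypes> %d samples x %d markers\n",
              length(x$sample_ids), length(x$marker_ids)))
  maf <- compute_maf(x)
  cat(sprintf("  MAF: min %.3f, median %.3f, max %.3f\n",
              min(maf), stats::median(maf), max(maf)))
  het <- mean(x$values == 1L)
  cat(sprintf("  heterozygous entries: %.1f%%\n", 100 * het))
  invisible(x)
}

#' @export
dim.gs_genotypes <- function(x) dim(x$values)

# subset samples (i) and/or markers (j); keeps metadata aligned
#' @export
`[.gs_genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$marker_ids)
  gs_genotypes(x$values[i, j, drop = FALSE],
               sample_ids = x$sample_ids[i],
               marker_ids = x$marker_ids[j],
               chromosome = if (!is.null(x$chromosome)) x$chromosome[j],
               position = if (!is.null(x$position)) x$position[j])
}

#' Minor allele frequency per marker
#'
#' MAF is `min(p, 1 - p)` where `p` is the allele-count frequency
#' `sum(counts) / (2 n)`; always in `[0, 0.5]`.
#'
#' @param G a `gs_genotypes` object.
#' @return Named numeric vector, one MAF per marker.
#' @export
compute_maf <- function(G) {
  stopifnot(inherits(G, "gs_genotypes"))
  p <- colSums(G$values) / (2 * nrow(G$values))
  maf <- pmin(p, 1 - p)
  names(maf) <- G$marker_ids
  maf
}

#' Filter markers by minor allele frequency
#'
#' Keeps exactly the markers with MAF >= `threshold` (the boundary is kept:
#' a filter that excludes markers *below* 10% retains one *at* 10%).
#' Marker order is preserved.
#'
#' @param G a `gs_genotypes` object.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @export
filter_maf <- function(G, threshold) {
  stopifnot(inherits(G, "gs_genotypes"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5)
    stop("threshold must be a single value in [0, 0.5]", call. = FALSE)
  keep <- compute_maf(G) >= threshold
  if (!any(keep))
    stop("MAF filter removed all markers", call. = FALSE)
  G[, which(keep)]
}

#' Remove duplicated markers
#'
#' Markers whose encoded value vectors are identical to an earlier marker
#' (by column order) are dropped; the first occurrence survives.
#'
#' @param G a `gs_genotypes` object.
#' @export
filter_duplicates <- function(G) {
  stopifnot(inherits(G, "gs_genotypes"))
  keep <- !duplicated(lapply(seq_len(ncol(G$values)),
                             function(j) G$values[, j]))
  G[, which(keep)]
}

#' Encode a genotype matrix for model input
#'
#' Three schemes are supported:
#' * `additive012` — identity on the stored 0/1/2 counts;
#' * `additive_centered` — counts minus 1, i.e. -1/0/1 (used by RR-BLUP);
#' * `onehot` — one indicator column per *observed genotype state* per
#'   marker (at most three); every row has exactly one active indicator per
#'   marker, so row sums equal the marker count.
#'
#' One-hot encoding of nucleotide identities (ACGT) is not possible from
#' additive counts, so genotype states stand in for them; `feature_group`
#' maps each output column back to its source marker.
#'
#' @param G a `gs_genotypes` object.
#' @param scheme one of `"additive012"`, `"additive_centered"`, `"onehot"`.
#' @return A `gs_encoded` object: list with `scheme`, `values` (numeric
#'   matrix), `marker_ids`, and for onehot `feature_group` (integer source
#'   marker index per column) and `feature_state` (the genotype state the
#'   column indicates).
#' @export
encode_genotypes <- function(G, scheme = c("additive012", "additive_centered", "onehot")) {
  stopifnot(inherits(G, "gs_genotypes"))
  scheme <- match.arg(scheme)
  V <- G$values
  if (scheme == "additive012") {
    out <- list(scheme = scheme, values = V + 0.0, marker_ids = G$marker_ids,
                feature_group = seq_along(G$marker_ids))
  } else if (scheme == "additive_centered") {
    out <- list(scheme = scheme, values = V - 1.0, marker_ids = G$marker_ids,
                feature_group = seq_along(G$marker_ids))
  } else {
    cols <- vector("list", ncol(V))
    group <- vector("list", ncol(V))
    state <- vector("list", ncol(V))
    for (j in seq_len(ncol(V))) {
      states <- sort(unique(V[, j]))
      ind <- vapply(states, function(s) as.numeric(V[, j] == s),
                    numeric(nrow(V)))
      colnames(ind) <- paste0(G$marker_ids[j], "_", states)
      cols[[j]] <- ind
      group[[j]] <- rep(j, length(states))
      state[[j]] <- states
    }
    out <- list(scheme = scheme, values = do.call(cbind, cols),
                marker_ids = G$marker_ids,
                feature_group = unlist(group), feature_state = unlist(state))
  }
  rownames(out$values) <- G$sample_ids
  structure(out, class = "gs_encoded")
}

#' Invert a one-hot encoding back to a genotype matrix
#'
#' @param E a `gs_encoded` object with `scheme == "onehot"`.
#' @param sample_ids sample ids for the reconstructed matrix.
#' @export
decode_onehot <- function(E, sample_ids = rownames(E$values)) {
  stopifnot(inherits(E, "gs_encoded"), E$scheme == "onehot")
  m <- length(E$marker_ids)
  V <- matrix(0L, nrow(E$values), m)
  for (j in seq_len(m)) {
    idx <- which(E$feature_group == j)
    states <- E$feature_state[idx]
    V[, j] <- as.integer(E$values[, idx, drop = FALSE] %*% states)
  }
  gs_genotypes(V, sample_ids = sample_ids, marker_ids = E$marker_ids)
}

#' Generate a synthetic genotype panel
#'
#' Draws biallelic markers whose empirical minor-allele frequencies fall in
#' `(maf_low, maf_high]`, emulating a prepared inbred panel: with
#' `homozygous_only = TRUE` (the default) genotypes are 0/2 as in a selfing
#' species. Linkage disequilibrium can be injected block-wise through a
#' shared latent Gaussian: markers inside a block of `ld_block_size`
#' consecutive markers share a latent factor with loading `sqrt(ld_rho)`,
#' so neighbouring markers are positively correlated while blocks remain
#' independent. Markers whose empirical MAF falls outside the target window
#' or that duplicate an earlier marker are redrawn.
#'
#' @param n_samples,n_markers panel dimensions.
#' @param maf_low,maf_high open/closed MAF bounds, `0 < maf_low < maf_high <= 0.5`.
#' @param homozygous_only if TRUE genotypes take values 0/2 only.
#' @param ld_block_size block length in markers; 0 disables LD.
#' @param ld_rho latent correlation within a block, in `[0, 1)`.
#' @param seed integer seed; equal seeds give bit-identical panels.
#' @return A `gs_genotypes` object.
#' @export
generate_genotypes <- function(n_samples, n_markers,
                               maf_low = 0.10, maf_high = 0.5,
                               homozygous_only = TRUE,
                               ld_block_size = 0, ld_rho = 0,
                               seed = 1L) {
  stopifnot(n_samples >= 2, n_markers >= 1)
  if (!(maf_low > 0 && maf_low < maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low < maf_high <= 0.5", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must be in [0, 1)", call. = FALSE)
  # smallest nonzero empirical MAF: one minor homozygote (1/n) or one het (1/2n)
  min_maf <- if (homozygous_only) 1 / n_samples else 1 / (2 * n_samples)
  if (min_maf > maf_high)
    stop("no representable MAF <= maf_high at this sample size", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  blocks <- if (ld_block_size > 0) {
    split(seq_len(n_markers),
          ceiling(seq_len(n_markers) / ld_block_size))
  } else {
    as.list(seq_len(n_markers))
  }

  draw_latent <- function(k) {
    # n_samples x k latent Gaussians equicorrelated at ld_rho within the block
    E <- matrix(stats::rnorm(n_samples * k), n_samples, k)
    if (ld_rho > 0 && k > 1) {
      shared <- stats::rnorm(n_samples)
      sqrt(ld_rho) * shared + sqrt(1 - ld_rho) * E
    } else E
  }

  V <- matrix(0L, n_samples, n_markers)
  seen <- new.env(parent = emptyenv())
  for (b in blocks) {
    k <- length(b)
    done <- rep(FALSE, k)
    tries <- 0L
    while (!all(done)) {
      tries <- tries + 1L
      if (tries > 200L)
        stop("could not realize requested MAF window; relax bounds or add samples",
             call. = FALSE)
      L <- draw_latent(k)
      target <- stats::runif(k, maf_low, maf_high)
      for (jj in which(!done)) {
        z <- L[, jj]
        if (homozygous_only) {
          # minor homozygote where latent exceeds its (1 - target) quantile
          g <- 2L * (z > stats::qnorm(1 - target[jj]))
        } else {
          # two allele draws from the same latent: split z into two pseudo-alleles
          z2 <- sqrt(0.5) * z + sqrt(0.5) * stats::rnorm(n_samples)
          thr <- stats::qnorm(1 - target[jj])
          g <- (z > thr) + (z2 > thr)
        }
        g <- as.integer(g)
        maf <- min(sum(g), 2 * n_samples - sum(g)) / (2 * n_samples)
        if (maf <= maf_low || maf > maf_high) next
        key <- paste(g, collapse = "")
        if (!is.null(seen[[key]])) next      # duplicate column: redraw
        seen[[key]] <- TRUE
        V[, b[jj]] <- g
        done[jj] <- TRUE
      }
    }
  }
  gs_genotypes(V,
               sample_ids = sprintf("S%04d", seq_len(n_samples)),
               marker_ids = sprintf("M%05d", seq_len(n_markers)))
}

# save/restore .Random.seed so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read / write the delimited genotype table
#'
#' The interchange format is a delimited text table (comma or tab,
#' auto-detected on read), UTF-8, with a header row
#' `sample_id,<marker_1>,...` and values in \{0,1,2\}. Malformed cells are
#' reported with their sample and marker.
#'
#' @param path file path.
#' @return `read_genotype_table()` returns a `gs_genotypes`;
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("empty genotype file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("genotype table needs a header 'sample_id,<marker ids>'", call. = FALSE)
  marker_ids <- header[-1]
  if (anyDuplicated(marker_ids))
    stop("duplicated marker id in header: ",
         marker_ids[duplicated(marker_ids)][1], call. = FALSE)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  sample_ids <- tab[[1]]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  V <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(V), nrow(V), ncol(V)))
  bad <- which(is.na(num) | !(num %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(V)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(V)) + 1L
    stop(sprintf("invalid genotype value '%s' at sample '%s', marker '%s' (row %d, column %d)",
                 V[bad[1]], sample_ids[i], marker_ids[j], i, j + 1L),
         call. = FALSE)
  }
  gs_genotypes(matrix(as.integer(num), nrow(V), ncol(V)),
               sample_ids = sample_ids, marker_ids = marker_ids)
}

#' @rdname read_genotype_table
#' @param G a `gs_genotypes` object to write.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_genotype_table <- function(G, path, sep = ",") {
  stopifnot(inherits(G, "gs_genotypes"))
  df <- data.frame(sample_id = G$sample_ids, G$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read / write the two-column phenotype table
#'
#' Format: delimited text with header `sample_id,value`.
#'
#' @param path file path.
#' @export
read_phenotype_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("phenotype table needs columns sample_id,value", call. = FALSE)
  y <- as.numeric(tab[[2]])
  if (anyNA(y))
    stop("non-numeric phenotype value at row ", which(is.na(y))[1], call. = FALSE)
  stats::setNames(y, as.character(tab[[1]]))
}

#' @rdname read_phenotype_table
#' @param y named numeric vector (names are sample ids).
#' @export
write_phenotype_table <- function(y, path) {
  df <- data.frame(sample_id = names(y), value = as.numeric(y))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
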