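#' Full feature-table column names
#'
#' Fixed, documented column order: the 11 interaction features, the 8
#' CPAASC class frequencies, then the dense mono- (26), di- (676) and
#' tripeptide (17,576) blocks in lexicographic order -- 18,297 feature
#' columns in total with the default 26-symbol alphabet.
#'
#' @param config Configuration list.
#' @return Character vector of feature names.
#' @export
feature_column_names <- function(config = default_config()) {
  c(interaction_feature_names(),
    paste0("cpaasc_", cpaasc_feature_names()),
    paste0("mono_", kmer_feature_names(1, config$alphabet)),
    paste0("di_", kmer_feature_names(2, config$alphabet)),
    paste0("tri_", kmer_feature_names(3, config$alphabet)))
}

#' Extract the full feature vector for one chain
#'
#' @param structure A \code{protein_structure}.
#' @param config Configuration list.
#' @return Named numeric vector over [feature_column_names()].
#' @export
extract_features <- function(structure, config = default_config()) {
  iv <- interaction_vector(structure, config)
  cp <- cpaasc_frequencies(structure$sequence, config)
  names(cp) <- paste0("cpaasc_", names(cp))
  blocks <- lapply(1:3, function(k) {
    v <- suppressWarnings(
      kmer_frequencies(structure$sequence, k, dense = TRUE,
                       alphabet = config$alphabet))
    names(v) <- paste0(c("mono_", "di_", "tri_")[k], names(v))
    v
  })
  c(iv, cp, blocks[[1]], blocks[[2]], blocks[[3]])
}

#' Extract features for every chain in a directory of PDB files
#'
#' Walks all \code{.pdb}/\code{.ent} files in \code{input_dir} (sorted
#' by name, so the result is independent of directory listing order),
#' splits each into chains, optionally pairs each file with a same-stem
#' MOL2 bond file from \code{mol2_dir}, and assembles the proteins x
#' features table. Files that fail to parse are logged and skipped; the
#' run manifest records per-file status, the configuration digest and
#' the package version.
#'
#' @param input_dir Directory containing PDB files.
#' @param config Configuration list.
#' @param mol2_dir Optional directory of MOL2 files named like the PDB
#'   stems.
#' @param min_residues Drop chains shorter than this (default 1, i.e.
#'   no filter).
#' @return A \code{feature_table}: list with \code{features} (data.frame,
#'   one row per chain, first column \code{protein_id}), \code{labels}
#'   (NULL until [attach_labels()]), and \code{manifest}.
#' @export
extract_all <- function(input_dir, config = default_config(),
                        mol2_dir = NULL, min_residues = 1) {
  files <- sort(list.files(input_dir, pattern = "\\.(pdb|ent)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no PDB files in ", input_dir)
  cols <- feature_column_names(config)
  rows <- list()
  status <- list()
  for (f in files) {
    res <- tryCatch({
      chains <- suppressWarnings(parse_pdb(f))
      if (!is.null(mol2_dir)) {
        m2 <- file.path(mol2_dir, paste0(
          sub("\\.(pdb|ent)$", "", basename(f), ignore.case = TRUE), ".mol2"))
        if (file.exists(m2) && length(chains) == 1) {
          chains[[1]] <- set_bond_graph(chains[[1]],
                                        parse_mol2(m2, chains[[1]]))
        }
      }
      for (id in names(chains)) {
        s <- chains[[id]]
        if (nrow(s$residues) < min_residues) next
        rows[[id]] <- extract_features(s, config)
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    if (res != "ok") message("skipping ", basename(f), " (", res, ")")
    status[[basename(f)]] <- res
  }
  if (length(rows) == 0) stop("no chain could be extracted from ", input_dir)
  mat <- do.call(rbind, rows)
  stopifnot(identical(colnames(mat), cols))
  features <- data.frame(protein_id = rownames(mat), mat,
                         row.names = NULL, check.names = FALSE,
                         stringsAsFactors = FALSE)
  manifest <- list(
    n_files = length(files),
    n_rows = nrow(features),
    file_status = status,
    config_digest = .config_digest(config),
    package_version = as.character(utils::packageVersion("protfeat"))
  )
  structure(list(features = features, labels = NULL, manifest = manifest),
            class = "feature_table")
}

.config_digest <- function(config) {
  # stable content hash without external digest packages
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
               collapse = "\n")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 257 + 1)) %% 2^31
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "proteins x",
      ncol(x$features) - 1, "features",
      if (!is.null(x$labels)) "| labeled" else "| unlabeled", "\n")
  invisible(x)
}

#' Attach class labels to a feature table
#'
#' Joins a two-column (id, label) mapping onto the table rows. Rows
#' without a mapping entry keep an NA label and are reported; duplicate
#' ids with conflicting labels are an error.
#'
#' @param table A \code{feature_table} from [extract_all()].
#' @param mapping Either a path to a two-column TSV (with or without a
#'   header) or a data.frame with columns id, label.
#' @return The table with \code{labels} set (named character vector,
#'   one entry per row).
#' @export
attach_labels <- function(table, mapping) {
  stopifnot(inherits(table, "feature_table"))
  if (is.character(mapping)) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE,
                                 col.names = c("id", "label"))
    if (identical(tolower(mapping$id[1]), "id")) {
      mapping <- mapping[-1, , drop = FALSE]
    }
  }
  names(mapping)[1:2] <- c("id", "label")
  dup <- unique(mapping$id[duplicated(mapping$id)])
  for (d in dup) {
    if (length(unique(mapping$label[mapping$id == d])) > 1) {
      stop("conflicting labels for id '", d, "' in mapping")
    }
  }
  mapping <- mapping[!duplicated(mapping$id), , drop = FALSE]
  lab <- mapping$label[match(table$features$protein_id, mapping$id)]
  if (all(is.na(lab))) stop("no id overlap between table and mapping")
  if (anyNA(lab)) {
    message(sum(is.na(lab)), " row(s) without a label retained as NA")
  }
  table$labels <- stats::setNames(lab, table$features$protein_id)
  message("label cardinality: ", length(unique(stats::na.omit(lab))))
  table
}

#' Write a feature table to TSV
#'
#' Header line plus one row per protein; deterministic formatting, so
#' re-running the same extraction yields byte-identical output.
#'
#' @param table A \code{feature_table}.
#' @param path Output TSV path.
#' @param manifest_path Optional path for the JSON run manifest.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path, manifest_path = NULL) {
  df <- table$features
  if (!is.null(table$labels)) df$label <- unname(table$labels)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) as.character(signif(v, 10)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(table$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}
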