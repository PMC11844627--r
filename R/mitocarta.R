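# MitoCarta3.0 pathway hierarchy: parsing, symbol harmonization, gene subsetting.

#' Load a MitoCarta-style pathway annotation table
#'
#' Parses the MitoCarta3.0 "MitoPathways" sheet (or any table in the same
#' dialect) into a queryable three-level pathway hierarchy. Each row is one
#' pathway with a hierarchy label such as
#' \code{"OXPHOS > Complex I > CI subunits"} and a delimited list of member
#' gene symbols. The full hierarchical path is used as the pathway id so that
#' duplicate short names at different levels stay distinct.
#'
#' @param pathway_file Path to a TSV/CSV (or, with \pkg{readxl} installed,
#'   XLSX) file with one row per pathway. Required columns (matched
#'   case-insensitively, first match wins): a pathway name column
#'   (\code{MitoPathway} / \code{pathway} / \code{name}), a hierarchy column
#'   (\code{MitoPathways Hierarchy} / \code{hierarchy}), and a gene column
#'   (\code{Genes} / \code{genes}). Genes are comma-separated within the cell.
#' @param species \code{"human"} or \code{"mouse"}; recorded on the object.
#' @param gene_file Optional path to a gene table (MitoCarta gene sheet) with
#'   a \code{Symbol} column; its symbols extend the gene universe beyond the
#'   union of pathway memberships.
#' @param sheet Sheet name or index when reading XLSX.
#'
#' @return A \code{mito_hierarchy} object: a list with \code{nodes} (a
#'   data.frame of \code{id}, \code{name}, \code{level}, \code{parent_id},
#'   \code{n_genes}), \code{genes} (named list of gene-symbol vectors keyed by
#'   pathway id), \code{gene_universe}, and \code{species}.
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_mini_mitocarta_pathways.tsv",
#'                  package = "mitotyper")
#' h <- load_mitocarta(f, species = "human")
#' h
load_mitocarta <- function(pathway_file, species = c("human", "mouse"),
                           gene_file = NULL, sheet = 1L) {
  species <- match.arg(species)
  tab <- read_annotation_table(pathway_file, sheet = sheet)

  name_col  <- pick_column(tab, c("mitopathway", "pathway", "name"))
  hier_col  <- pick_column(tab, c("mitopathways hierarchy", "hierarchy", "mitopathway hierarchy"))
  gene_col  <- pick_column(tab, c("genes", "gene", "symbols"))
  if (is.na(name_col) || is.na(hier_col) || is.na(gene_col)) {
    stop("pathway file must have pathway-name, hierarchy and gene columns; found: ",
         paste(names(tab), collapse = ", "))
  }

  hier_raw <- trimws(as.character(tab[[hier_col]]))
  names_raw <- trimws(as.character(tab[[name_col]]))
  segs <- strsplit(hier_raw, ">", fixed = TRUE)
  segs <- lapply(segs, trimws)
  levels <- vapply(segs, length, integer(1))
  bad <- which(levels < 1L | levels > 3L | vapply(segs, function(s) any(!nzchar(s)), logical(1)))
  if (length(bad)) {
    stop("malformed hierarchy label in row ", bad[1], ": '", hier_raw[bad[1]], "'")
  }

  ids <- vapply(segs, paste, character(1), collapse = " > ")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parent_ids <- vapply(segs, function(s) {
    if (length(s) == 1L) NA_character_ else paste(s[-length(s)], collapse = " > ")
  }, character(1))

  orphans <- which(!is.na(parent_ids) & !(parent_ids %in% ids))
  if (length(orphans)) {
    stop("orphan level-", levels[orphans[1]], " pathway '", ids[orphans[1]],
         "': parent '", parent_ids[orphans[1]], "' not present")
  }

  genes <- lapply(as.character(tab[[gene_col]]), function(g) {
    g <- unlist(strsplit(g, "[,;]"))
    g <- trimws(g)
    unique(g[nzchar(g)])
  })
  names(genes) <- ids
  empty <- which(vapply(genes, length, integer(1)) == 0L)
  if (length(empty)) {
    stop("pathway '", ids[empty[1]], "' has an empty gene list")
  }

  universe <- unique(unlist(genes, use.names = FALSE))
  if (!is.null(gene_file)) {
    gt <- read_annotation_table(gene_file, sheet = sheet)
    sym_col <- pick_column(gt, c("symbol", "gene", "symbols"))
    if (is.na(sym_col)) stop("gene file must have a Symbol column")
    universe <- unique(c(universe, trimws(as.character(gt[[sym_col]]))))
    universe <- universe[nzchar(universe)]
  }

  nodes <- data.frame(
    id = ids,
    name = names_raw,
    level = levels,
    parent_id = parent_ids,
    n_genes = vapply(genes, length, integer(1)),
    stringsAsFactors = FALSE
  )
  h <- structure(
    list(nodes = nodes, genes = genes, gene_universe = universe, species = species),
    class = "mito_hierarchy"
  )
  check_gene_nesting(h, action = "warning")
  h
}

# Parent gene sets should contain the union of their children's genes.
check_gene_nesting <- function(h, action = c("warning", "error", "none")) {
  action <- match.arg(action)
  if (action == "none") return(invisible(TRUE))
  kids <- split(h$nodes$id, h$nodes$parent_id)
  for (p in names(kids)) {
    child_genes <- unique(unlist(h$genes[kids[[p]]], use.names = FALSE))
    missing <- setdiff(child_genes, h$genes[[p]])
    if (length(missing)) {
      msg <- paste0("pathway '", p, "' lacks ", length(missing),
                    " gene(s) present in its children (e.g. ", missing[1], ")")
      if (action == "error") stop(msg) else warning(msg, call. = FALSE)
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

read_annotation_table <- function(path, sheet = 1L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package; export the sheet to TSV instead")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "")
  }
}

pick_column <- function(tab, candidates) {
  nm <- tolower(trimws(names(tab)))
  for (cand in candidates) {
    i <- match(cand, nm)
    if (!is.na(i)) return(i)
  }
  NA_integer_
}

#' @export
print.mito_hierarchy <- function(x, ...) {
  cat("MitoPathway hierarchy (", x$species, "): ",
      nrow(x$nodes), " pathways on levels 1-3, ",
      length(x$gene_universe), " genes in universe\n", sep = "")
  tab <- table(factor(x$nodes$level, levels = 1:3))
  cat("  level 1: ", tab[[1]], "  level 2: ", tab[[2]], "  level 3: ", tab[[3]], "\n", sep = "")
  cat("  genes per pathway: median ", stats::median(x$nodes$n_genes),
      ", range ", min(x$nodes$n_genes), "-", max(x$nodes$n_genes), "\n", sep = "")
  invisible(x)
}

#' Pathway gene sets
#'
#' @param hierarchy A \code{mito_hierarchy}.
#' @param id Pathway id (full hierarchical path) or short name (must be
#'   unambiguous).
#' @return Character vector of member gene symbols.
#' @export
pathway_genes <- function(hierarchy, id) {
  stopifnot(inherits(hierarchy, "mito_hierarchy"))
  key <- resolve_pathway_id(hierarchy, id)
  hierarchy$genes[[key]]
}

# Accept either the full path id or a unique short name.
resolve_pathway_id <- function(hierarchy, id) {
  if (id %in% hierarchy$nodes$id) return(id)
  hits <- hierarchy$nodes$id[hierarchy$nodes$name == id]
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L) {
    stop("pathway name '", id, "' is ambiguous; use a full id: ",
         paste(hits, collapse = " | "))
  }
  stop("unknown pathway: '", id, "'")
}

#' Serialize / restore a pathway hierarchy as JSON
#'
#' The JSON round trip preserves node ids, levels, parents and gene sets
#' exactly.
#'
#' @param hierarchy A \code{mito_hierarchy}.
#' @param path Output (input) file path.
#' @return \code{write_hierarchy_json} returns \code{path} invisibly;
#'   \code{read_hierarchy_json} returns a \code{mito_hierarchy}.
#' @export
write_hierarchy_json <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "mito_hierarchy"))
  payload <- list(
    species = hierarchy$species,
    gene_universe = hierarchy$gene_universe,
    nodes = lapply(seq_len(nrow(hierarchy$nodes)), function(i) {
      n <- hierarchy$nodes[i, ]
      list(id = n$id, name = n$name, level = n$level,
           parent_id = if (is.na(n$parent_id)) NULL else n$parent_id,
           genes = hierarchy$genes[[n$id]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hierarchy_json
#' @export
read_hierarchy_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- do.call(rbind, lapply(payload$nodes, function(n) {
    p <- n$parent_id
    data.frame(id = n$id, name = n$name, level = as.integer(n$level),
               parent_id = if (is.null(p) || !length(p)) NA_character_ else p,
               n_genes = length(n$genes), stringsAsFactors = FALSE)
  }))
  genes <- lapply(payload$nodes, function(n) unlist(n$genes, use.names = FALSE))
  names(genes) <- nodes$id
  structure(
    list(nodes = nodes, genes = genes,
         gene_universe = unlist(payload$gene_universe, use.names = FALSE),
         species = payload$species),
    class = "mito_hierarchy"
  )
}

#' Gene-symbol alias table
#'
#' Builds the rewrite table used to harmonize input gene symbols against the
#' MitoCarta universe. Two rules ship by default, matching the fixes needed
#' for RNA-seq exports that strip mtDNA prefixes: (1) explicit renames
#' (\code{C12orf10 -> MYG1}); (2) restoration of the \code{"MT-"} prefix when
#' the bare stem (e.g. \code{ND1}) is absent from the universe but
#' \code{MT-ND1} is present. Extensions are supplied as a named character
#' vector or a two-column file (\code{from}, \code{to}).
#'
#' @param extra Named character vector (\code{from = to}) or path to a
#'   two-column TSV/CSV of additional explicit renames. Applied before the
#'   built-in mapping so user entries win.
#' @param mt_prefix Keep the MT- prefix restoration rule active.
#' @return An \code{alias_table} object.
#' @export
alias_table <- function(extra = NULL, mt_prefix = TRUE) {
  mapping <- c(C12orf10 = "MYG1")
  if (!is.null(extra)) {
    if (is.character(extra) && is.null(names(extra)) && length(extra) == 1L) {
      tab <- read_annotation_table(extra)
      if (ncol(tab) < 2L) stop("alias file needs two columns (from, to)")
      user <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
    } else if (is.character(extra) && !is.null(names(extra))) {
      user <- extra
    } else {
      stop("'extra' must be a named character vector or a file path")
    }
    mapping <- c(user, mapping[setdiff(names(mapping), names(user))])
  }
  # idempotence: a target of one rename must not itself be renamed
  chained <- intersect(unname(mapping), names(mapping))
  if (length(chained)) {
    stop("alias mapping is not idempotent; chained symbol(s): ",
         paste(chained, collapse = ", "))
  }
  structure(list(mapping = mapping, mt_prefix = isTRUE(mt_prefix)),
            class = "alias_table")
}

#' Resolve gene symbols against a pathway hierarchy
#'
#' Applies the alias mapping and rewrite rules, then matches exactly (no case
#' folding) against the hierarchy's gene universe. Every input symbol ends up
#' either in \code{resolved} or in \code{unmapped}; nothing is dropped
#' silently.
#'
#' @param symbols Character vector of raw gene symbols.
#' @param aliases An [alias_table()].
#' @param hierarchy A \code{mito_hierarchy}.
#' @return A list with \code{resolved} (data.frame \code{raw}, \code{symbol})
#'   and \code{unmapped} (character vector of inputs with no universe match).
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_mini_mitocarta_pathways.tsv",
#'                  package = "mitotyper")
#' h <- load_mitocarta(f)
#' resolve_symbols(c("MT-CO1", "ND1"), alias_table(), h)
resolve_symbols <- function(symbols, aliases = alias_table(), hierarchy) {
  stopifnot(inherits(aliases, "alias_table"), inherits(hierarchy, "mito_hierarchy"))
  out <- apply_aliases(symbols, aliases, hierarchy$gene_universe)
  ok <- out %in% hierarchy$gene_universe
  list(
    resolved = data.frame(raw = symbols[ok], symbol = out[ok],
                          stringsAsFactors = FALSE),
    unmapped = symbols[!ok]
  )
}

apply_aliases <- function(symbols, aliases, universe) {
  out <- symbols
  hit <- match(out, names(aliases$mapping))
  out[!is.na(hit)] <- unname(aliases$mapping[hit[!is.na(hit)]])
  if (aliases$mt_prefix) {
    need <- !(out %in% universe) & (paste0("MT-", out) %in% universe)
    out[need] <- paste0("MT-", out[need])
  }
  out
}

#' Subset an expression matrix to mitochondrial genes
#'
#' Harmonizes the matrix's row symbols via the alias table and keeps the rows
#' that map into the hierarchy's gene universe. Rows are re-keyed to the
#' canonical symbols.
#'
#' @param expr A gene-by-sample matrix (rows named by gene symbol), e.g. from
#'   [read_matrix()].
#' @param hierarchy A \code{mito_hierarchy}.
#' @param aliases An [alias_table()].
#' @return A list: \code{expr} (the mitochondrial submatrix),
#'   \code{missing_genes} (universe genes absent from the input), and
#'   \code{n_found}.
#' @export
mito_subset <- function(expr, hierarchy, aliases = alias_table()) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  res <- resolve_symbols(rownames(expr), aliases, hierarchy)
  if (nrow(res$resolved) == 0L) {
    stop("no mitochondrial genes found; are the row names gene symbols in the ",
         "same identifier space as the annotation?")
  }
  keep <- match(res$resolved$raw, rownames(expr))
  sub <- expr[keep, , drop = FALSE]
  rownames(sub) <- res$resolved$symbol
  if (anyDuplicated(rownames(sub))) {
    dup <- unique(rownames(sub)[duplicated(rownames(sub))])
    stop("multiple input rows map to the same canonical symbol(s): ",
         paste(dup, collapse = ", "))
  }
  list(
    expr = sub,
    missing_genes = setdiff(hierarchy$gene_universe, rownames(sub)),
    n_found = nrow(sub)
  )
}
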