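#' Tanglegram: host tree, parasite tree, leaf associations
#'
#' The input of the dated tree reconciliation problem: a dated host tree, a
#' parasite tree, and the association map phi from parasite leaves to host
#' leaves. Each parasite leaf inhabits exactly one host leaf (Ronquist's
#' single-host constraint); several parasite leaves may share one host leaf.
#'
#' @param host a [cophy_tree()] or `dated_cophy_tree` (undated hosts receive
#'   the canonical dating of [apply_dating()]).
#' @param parasite a [cophy_tree()].
#' @param associations either a two-column data frame (`parasite`, `host`
#'   leaf labels) or a named character vector `c(parasiteLeaf = hostLeaf)`.
#' @return A `tanglegram` object.
#' @export
#' @examples
#' h <- parse_newick("((a,b)x,c)r;")
#' p <- parse_newick("((A,B)y,C)z;")
#' tanglegram(h, p, c(A = "a", B = "b", C = "c"))
tanglegram <- function(host, parasite, associations) {
  if (!inherits(host, "cophy_tree")) host <- as_cophy_tree(host)
  host <- apply_dating(host)
  if (!inherits(parasite, "cophy_tree")) parasite <- as_cophy_tree(parasite)
  if (is.character(associations)) {
    associations <- tibble::tibble(parasite = names(associations),
                                   host = unname(associations))
  }
  associations <- tibble::as_tibble(associations[, c("parasite", "host")])
  p_tips <- parasite$tip_label
  counts <- table(factor(associations$parasite, levels = p_tips))
  if (any(counts != 1L)) {
    off <- names(counts)[counts != 1L]
    extra <- setdiff(associations$parasite, p_tips)
    stop("each parasite leaf needs exactly one host association; offenders: ",
         paste(unique(c(off, extra)), collapse = ", "))
  }
  if (length(bad <- setdiff(associations$parasite, p_tips))) {
    stop("association names unknown parasite leaf '", bad[1L], "'")
  }
  if (length(bad <- setdiff(associations$host, host$tip_label))) {
    stop("association names unknown host leaf '", bad[1L], "'")
  }
  phi <- integer(parasite$n_nodes)
  phi[match(associations$parasite, p_tips)] <-
    match(associations$host, host$tip_label)
  structure(list(host = host, parasite = parasite, phi = phi,
                 associations = associations[order(match(associations$parasite,
                                                         p_tips)), ]),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("<tanglegram> host: ", x$host$n_tips, " tips; parasite: ",
      x$parasite$n_tips, " tips; ", nrow(x$associations),
      " associations\n", sep = "")
  invisible(x)
}

# ensure every host internal node carries a unique label (needed to address
# DATING entries); synthesizes N1..N(n-1) when absent or duplicated
ensure_internal_labels <- function(tree) {
  lbl <- tree$node_label
  if (anyNA(lbl) || any(!nzchar(lbl)) || anyDuplicated(lbl)) {
    tree$node_label <- paste0("N", seq_len(tree$n_tips - 1L))
  }
  tree
}

#' Read a tanglegram
#'
#' Two sources are supported: the package's NEXUS dialect (blocks `TREES`
#' with `TREE HOST = ...;` and `TREE PARASITE = ...;`, `ASSOCIATIONS` with
#' comma-separated `parasiteLeaf : hostLeaf` pairs, and an optional `DATING`
#' block of `hostInternalLabel = rank;` entries), or a pair of Newick files
#' plus a two-column tab-separated association table
#' (`parasite_leaf<TAB>host_leaf`, no header).
#'
#' @param file path to a NEXUS file.
#' @param text NEXUS text (alternative to `file`).
#' @param host,parasite,assoc paths to host Newick, parasite Newick and the
#'   association TSV (alternative to NEXUS input).
#' @return A [tanglegram()], host dated (explicit `DATING` block or the
#'   canonical dating).
#' @export
read_tanglegram <- function(file = NULL, text = NULL, host = NULL,
                            parasite = NULL, assoc = NULL) {
  if (!is.null(host) || !is.null(parasite) || !is.null(assoc)) {
    if (is.null(host) || is.null(parasite) || is.null(assoc)) {
      stop("newick+tsv input needs all of `host`, `parasite`, `assoc`")
    }
    h <- parse_newick(file = host)
    p <- parse_newick(file = parasite)
    a <- utils::read.table(assoc, sep = "\t", header = FALSE,
                           col.names = c("parasite", "host"),
                           colClasses = "character")
    return(tanglegram(h, p, a))
  }
  if (is.null(text)) {
    if (is.null(file)) stop("supply `file`, `text`, or newick+tsv paths")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    stop("not a NEXUS source: missing #NEXUS header")
  }
  grab1 <- function(pattern) {
    m <- regmatches(text, regexpr(pattern, text, perl = TRUE,
                                  ignore.case = TRUE))
    if (!length(m)) NULL else sub(pattern, "\\1", m, perl = TRUE,
                                  ignore.case = TRUE)
  }
  h_nwk <- grab1("TREE\\s+HOST\\s*=\\s*([^;]+);")
  p_nwk <- grab1("TREE\\s+PARASITE\\s*=\\s*([^;]+);")
  if (is.null(h_nwk) || is.null(p_nwk)) {
    stop("NEXUS must declare TREE HOST and TREE PARASITE")
  }
  a_blk <- grab1("(?s)BEGIN\\s+ASSOCIATIONS\\s*;(.*?)END\\s*;")
  if (is.null(a_blk)) stop("NEXUS must contain an ASSOCIATIONS block")
  entries <- strsplit(gsub("[;\\s]+$", "", trimws(a_blk), perl = TRUE),
                      ",")[[1L]]
  parts <- strsplit(trimws(entries), "\\s*:\\s*")
  if (any(lengths(parts) != 2L)) {
    stop("malformed association entry: '", entries[lengths(parts) != 2L][1L],
         "'")
  }
  assoc_df <- tibble::tibble(parasite = vapply(parts, `[`, "", 1L),
                             host = vapply(parts, `[`, "", 2L))
  h <- parse_newick(paste0(trimws(h_nwk), ";"))
  p <- parse_newick(paste0(trimws(p_nwk), ";"))
  d_blk <- grab1("(?s)BEGIN\\s+DATING\\s*;(.*?)END\\s*;")
  if (!is.null(d_blk)) {
    d_entries <- strsplit(trimws(d_blk), ";")[[1L]]
    d_entries <- d_entries[nzchar(trimws(d_entries))]
    kv <- strsplit(trimws(d_entries), "\\s*=\\s*")
    if (any(lengths(kv) != 2L)) stop("malformed DATING entry")
    ranks <- as.integer(vapply(kv, `[`, "", 2L))
    names(ranks) <- vapply(kv, `[`, "", 1L)
    h <- apply_dating(h, ranks)
  }
  tanglegram(h, p, assoc_df)
}

#' Write a tanglegram
#'
#' Serializes to the NEXUS dialect read by [read_tanglegram()] (including a
#' `DATING` block with exactly one entry per host internal node, ordered by
#' rank) or to a Newick pair plus association TSV. Output is deterministic
#' and reparses to an equal tanglegram; a second write of the reread object
#' is byte-identical.
#'
#' @param tg a [tanglegram()].
#' @param file optional output path (NEXUS) or path prefix (`newick+tsv`,
#'   writing `<prefix>.host.nwk`, `<prefix>.parasite.nwk`, `<prefix>.tsv`).
#' @param format `"nexus"` (default) or `"newick+tsv"`.
#' @return The NEXUS text (invisibly when written to `file`), or for
#'   `"newick+tsv"` a named character vector of the three texts.
#' @export
write_tanglegram <- function(tg, file = NULL,
                             format = c("nexus", "newick+tsv")) {
  format <- match.arg(format)
  if (nrow(tg$associations) == 0L) stop("tanglegram has no associations")
  host <- ensure_internal_labels(tg$host)
  if (format == "newick+tsv") {
    out <- c(host = write_newick(host),
             parasite = write_newick(tg$parasite),
             assoc = paste0(tg$associations$parasite, "\t",
                            tg$associations$host, collapse = "\n"))
    if (!is.null(file)) {
      writeLines(out[["host"]], paste0(file, ".host.nwk"))
      writeLines(out[["parasite"]], paste0(file, ".parasite.nwk"))
      writeLines(out[["assoc"]], paste0(file, ".tsv"))
      return(invisible(out))
    }
    return(out)
  }
  n <- host$n_tips
  internals <- (n + 1L):host$n_nodes
  ord <- internals[order(host$rank[internals])]
  dating <- paste0(vapply(ord, function(v) node_name(host, v), ""),
                   " = ", host$rank[ord], ";")
  txt <- paste0(
    "#NEXUS\n",
    "BEGIN TREES;\n",
    "TREE HOST = ", sub(";$", "", write_newick(host)), ";\n",
    "TREE PARASITE = ", sub(";$", "", write_newick(tg$parasite)), ";\n",
    "END;\n",
    "BEGIN ASSOCIATIONS;\n",
    paste0(tg$associations$parasite, " : ", tg$associations$host,
           collapse = ", "), ";\n",
    "END;\n",
    "BEGIN DATING;\n",
    paste(dating, collapse = "\n"), "\n",
    "END;\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}
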