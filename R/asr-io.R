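# Tree and character-matrix I/O for the ordered 3-state tooth-crown
# character.  Trees are ape "phylo" objects (rooted, polytomies permitted);
# character data are named lists mapping each taxon to a non-empty subset of
# the state alphabet (missing / ambiguous = the full set).

#' Read a rooted tree (Newick or NEXUS)
#'
#' Polytomies are preserved.  Trees without branch lengths get uniform
#' length 1 on every branch when `uniformLengths` is TRUE (the default used
#' by the likelihood machinery, where the length unit is absorbed by the
#' rate).
#'
#' @param source file path or a Newick string.
#' @param uniformLengths add unit branch lengths when none are present.
#' @return an ape `phylo` object.
#' @export
readTreeFile <- function(source, uniformLengths = TRUE) {
  tr <- if (file.exists(source)) {
    first <- toupper(trimws(readLines(source, n = 1L, warn = FALSE)))
    if (startsWith(first, "#NEXUS")) ape::read.nexus(source)
    else ape::read.tree(source)
  } else {
    ape::read.tree(text = source)
  }
  if (is.null(tr)) stop("could not parse tree from ", source)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  # the basal node is taken as the root; a basal multifurcation is a rooted
  # polytomy here (ape's is.rooted cannot tell the two apart)
  if (anyDuplicated(tr$tip.label)) stop("tip labels must be unique")
  if (is.null(tr$edge.length) && uniformLengths)
    tr$edge.length <- rep(1, nrow(tr$edge))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tr
}

# parse one cell token ("0", "?", "-", "{01}", "(02)", "0/1", "01") into a
# state subset
.parse_state_token <- function(tok, states) {
  tok <- gsub("[{}() ]", "", tok)
  tok <- gsub("/", "", tok)
  if (tok %in% c("?", "-", "")) return(states)
  s <- as.integer(strsplit(tok, "")[[1]])
  if (any(is.na(s)) || !all(s %in% states))
    stop("unparseable state token: ", tok)
  sort(unique(s))
}

#' Read a taxon-by-character state matrix
#'
#' Accepts CSV (columns `taxon` and `state`; a state cell may be a single
#' digit, a multi-digit ambiguity set like `01` or `{01}` or `0/1`, or `?`
#' for missing) or a NEXUS CHARACTERS/DATA block (symbols 0-9, `{}`/`()`
#' ambiguity groups, `?`/`-` missing); for multi-character NEXUS matrices,
#' `charIndex` selects the character (e.g. a posterior tooth-crown-shape
#' column).
#'
#' @param source file path (CSV or NEXUS).
#' @param states integer state alphabet (default `0:2`: conical, rounded,
#'   flat).
#' @param charIndex 1-based character column for NEXUS matrices.
#' @return named list: taxon -> sorted integer state subset.
#' @export
readCharMatrix <- function(source, states = 0:2, charIndex = 1L) {
  first <- toupper(trimws(readLines(source, n = 1L, warn = FALSE)))
  if (startsWith(first, "#NEXUS"))
    return(.read_nexus_chars(source, states, charIndex))
  df <- read.csv(source, stringsAsFactors = FALSE,
                 colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("taxon", "state") %in% names(df)))
    stop("CSV must have columns 'taxon' and 'state'")
  out <- lapply(df$state, .parse_state_token, states = states)
  names(out) <- df$taxon
  if (anyDuplicated(names(out))) stop("duplicate taxa in matrix")
  out
}

# minimal NEXUS MATRIX parser: one taxon per line, contiguous state string
# with {} or () ambiguity groups
.read_nexus_chars <- function(path, states, charIndex) {
  txt <- readLines(path, warn = FALSE)
  lo <- grep("^\\s*matrix\\s*$", txt, ignore.case = TRUE)
  hi <- grep("^\\s*;", txt)
  if (!length(lo)) stop("no MATRIX block found in ", path)
  hi <- hi[hi > lo[1]][1]
  if (is.na(hi)) stop("unterminated MATRIX block in ", path)
  rows <- trimws(txt[(lo[1] + 1L):(hi - 1L)])
  rows <- rows[nzchar(rows) & !startsWith(rows, "[")]
  out <- list()
  for (r in rows) {
    mm <- regmatches(r, regexec("^('[^']+'|\\S+)\\s+(\\S+)$", r))[[1]]
    if (length(mm) != 3L) stop("unparseable matrix row: ", r)
    taxon <- gsub("^'|'$", "", mm[2])
    seqs <- mm[3]
    toks <- regmatches(seqs, gregexpr("\\{[^}]*\\}|\\([^)]*\\)|.", seqs))[[1]]
    if (charIndex > length(toks))
      stop("charIndex ", charIndex, " beyond ", length(toks),
           " characters for taxon ", taxon)
    out[[taxon]] <- .parse_state_token(toks[charIndex], states)
  }
  out
}

#' Write a character matrix as CSV
#'
#' @param charMatrix named list of integer state subsets.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCharMatrix <- function(charMatrix, path) {
  df <- data.frame(taxon = names(charMatrix),
                   state = vapply(charMatrix, paste, "", collapse = ""),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# check tip/matrix consistency; returns the matrix restricted+ordered to tips
.match_tips <- function(tree, charMatrix, states) {
  tips <- tree$tip.label
  missingTips <- setdiff(tips, names(charMatrix))
  if (length(missingTips))
    stop("taxa in tree but not in matrix: ",
         paste(missingTips, collapse = ", "))
  extra <- setdiff(names(charMatrix), tips)
  if (length(extra))
    .log_msg("matrix taxa not in tree (ignored): %s",
             paste(extra, collapse = ", "))
  cm <- charMatrix[tips]
  bad <- names(cm)[vapply(cm, function(s)
    length(s) == 0 || !all(s %in% states), logical(1))]
  if (length(bad))
    stop("invalid state sets for: ", paste(bad, collapse = ", "))
  cm
}

#' Per-node results as a table
#'
#' @param result a [ParsimonyResult-class] or [MkResult-class].
#' @param tree the `phylo` the result was computed on.
#' @return a data.frame with one row per node (ape numbering): tip/internal
#'   labels plus MPR state sets or marginal probabilities.
#' @export
asrTable <- function(result, tree) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", (nTip + 1L):nNode))
  df <- data.frame(node = seq_len(nNode), label = labels,
                   isTip = seq_len(nNode) <= nTip,
                   stringsAsFactors = FALSE)
  if (is(result, "ParsimonyResult")) {
    df$mprSet <- vapply(result@mprSets, paste, "", collapse = "")
  } else {
    for (s in result@states)
      df[[paste0("p", s)]] <- result@marginals[, s + 1L]
  }
  df
}

#' Export an ASR result as JSON
#'
#' @param result a [ParsimonyResult-class] or [MkResult-class].
#' @param tree the `phylo` used.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
asrToJson <- function(result, tree, path) {
  tab <- asrTable(result, tree)
  payload <- list(perNode = tab)
  if (is(result, "ParsimonyResult")) {
    payload$minCost <- result@minCost
    payload$originRange <- result@originRange
  } else {
    payload$rateHat <- result@rateHat
    payload$logLik <- result@logLik
    payload$mlOriginRange <- result@mlOriginRange
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Annotated Newick export with per-node state comments
#'
#' Writes the tree with node labels replaced by bracketed state annotations
#' (MPR sets or argmax marginal states).
#'
#' @param result a [ParsimonyResult-class] or [MkResult-class].
#' @param tree the `phylo` used.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
asrAnnotatedNewick <- function(result, tree, path) {
  nTip <- length(tree$tip.label)
  ann <- if (is(result, "ParsimonyResult")) {
    vapply(result@mprSets[(nTip + 1L):(nTip + tree$Nnode)],
           paste, "", collapse = "")
  } else {
    apply(result@marginals[(nTip + 1L):(nTip + tree$Nnode), , drop = FALSE],
          1, function(p) paste(result@states[p >= max(p) - 1e-12],
                               collapse = ""))
  }
  tree$node.label <- paste0("S", ann)
  ape::write.tree(tree, file = path)
  invisible(path)
}
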