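#' Parse a gene-reaction rule string
#'
#' Gene-reaction rules describe which gene products a reaction needs:
#' `AND` joins subunits of a complex, `OR` joins isozymes or paralogous
#' family members that can each carry the reaction. Parsing is by recursive
#' descent with the usual precedence (`AND` binds tighter than `OR`) and
#' parentheses; keywords are case-insensitive and `&`/`|` are accepted as
#' synonyms. Consecutive same-operator nodes are flattened, so
#' `A or B or C` is a single OR node with three children.
#'
#' @param rule character scalar; `""` or `NA` yield the empty tree.
#' @return a `gpr` object: either `NULL` (empty rule), a leaf
#'   `list(op = "leaf", gene = <id>)`, or `list(op = "and"|"or",
#'   args = <list of gpr>)`.
#' @export
#' @examples
#' parse_gpr("(Hk1 and Pfkl) or Pkm")
parse_gpr <- function(rule) {
  if (length(rule) != 1) stop("parse_gpr() expects a single rule string")
  if (is.na(rule) || !nzchar(trimws(rule))) {
    return(structure(list(), class = "gpr"))
  }
  tokens <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$tokens)) {
    stop("stray token in gene-reaction rule near '", st$tokens[st$pos], "'")
  }
  structure(tree, class = "gpr")
}

gpr_tokenize <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  bad <- grepl("[()]", tokens) & !tokens %in% c("(", ")")
  if (any(bad)) stop("malformed token in gene-reaction rule: ", tokens[bad][1])
  tokens
}

gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NA_character_ else st$tokens[st$pos]
}

gpr_take <- function(st) {
  tok <- gpr_peek(st)
  st$pos <- st$pos + 1L
  tok
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_and(st)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_take(st)
    args <- c(args, list(gpr_parse_atom(st)))
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_take(st)
  if (is.na(tok)) stop("unexpected end of gene-reaction rule")
  if (tok == "(") {
    inner <- gpr_parse_or(st)
    if (!identical(gpr_take(st), ")")) {
      stop("unbalanced parentheses in gene-reaction rule")
    }
    return(inner)
  }
  if (tok %in% c(")", "and", "or", "AND", "OR")) {
    stop("unexpected token '", tok, "' in gene-reaction rule")
  }
  list(op = "leaf", gene = tok)
}

# collapse single-child nodes and flatten nested same-op nodes
gpr_node <- function(op, args) {
  if (length(args) == 1) return(args[[1]])
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' Render a gene-reaction rule tree back to a string
#'
#' Inverse of [parse_gpr()] up to whitespace: `parse_gpr(gpr_render(x))`
#' reproduces `x`.
#'
#' @param expr a `gpr` tree.
#' @return character scalar (`""` for the empty tree).
#' @export
gpr_render <- function(expr) {
  if (is.null(expr) || length(expr) == 0) return("")
  render <- function(node, parent_op = NULL) {
    if (node$op == "leaf") return(node$gene)
    sep <- paste0(" ", node$op, " ")
    inner <- paste(vapply(node$args, render, "", parent_op = node$op),
                   collapse = sep)
    needs_paren <- !is.null(parent_op) && parent_op != node$op
    if (needs_paren) paste0("(", inner, ")") else inner
  }
  render(unclass(expr))
}

#' Genes referenced by a rule tree
#' @param expr a `gpr` tree.
#' @return character vector of unique gene ids (empty for the empty tree).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr) || length(expr) == 0) return(character())
  walk <- function(node) {
    if (node$op == "leaf") return(node$gene)
    unlist(lapply(node$args, walk))
  }
  unique(walk(unclass(expr)))
}

#' Effective reaction abundance by the minsum rule
#'
#' Aggregates protein abundances over a gene-reaction rule: an `AND` node
#' (complex) takes the minimum of its children, an `OR` node (isozymes)
#' takes their sum. Genes absent from `abundance` contribute 0, so a complex
#' with a missing subunit is blocked; missing ids are recorded in the
#' `missing_genes` attribute of the result.
#'
#' @param expr a `gpr` tree from [parse_gpr()].
#' @param abundance named numeric vector, gene id -> abundance (>= 0).
#' @return numeric scalar (`NA` for the empty tree, meaning "no enzyme
#'   information"), with attribute `missing_genes`.
#' @export
#' @examples
#' minsum(parse_gpr("(A and B) or C"), c(A = 2, B = 3, C = 10)) # 12
minsum <- function(expr, abundance) {
  if (is.null(expr) || length(expr) == 0) {
    return(structure(NA_real_, missing_genes = character()))
  }
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  missing <- setdiff(gpr_genes(expr), names(abundance))
  eval_node <- function(node) {
    if (node$op == "leaf") {
      if (!node$gene %in% names(abundance)) return(0)
      a <- abundance[[node$gene]]
      if (is.na(a)) 0 else a
    } else {
      vals <- vapply(node$args, eval_node, 0)
      if (node$op == "and") min(vals) else sum(vals)
    }
  }
  structure(eval_node(unclass(expr)), missing_genes = missing)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Effective abundance for every reaction of a model
#'
#' Applies [parse_gpr()] + [minsum()] to each reaction's rule string.
#'
#' @param model a [metabolic_model()].
#' @param abundance named numeric vector, gene id -> abundance.
#' @return tibble with `reaction_id`, `effective` (`NA` for gene-free
#'   reactions), `n_missing_genes`.
#' @export
reaction_abundance <- function(model, abundance) {
  stopifnot(inherits(model, "metabolic_model"))
  purrr::map_dfr(seq_len(nrow(model$reactions)), function(i) {
    expr <- parse_gpr(model$reactions$gpr[i])
    eff <- minsum(expr, abundance)
    tibble::tibble(reaction_id = model$reactions$id[i],
                   effective = as.numeric(eff),
                   n_missing_genes = length(attr(eff, "missing_genes")))
  })
}
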