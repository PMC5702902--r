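# Gene-protein-reaction (GPR) rules: Boolean expressions over gene ids.
# Subunits of a complex are joined by AND, isoenzymes by OR; parentheses group.

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(data.frame(token = character(0), pos = integer(0)))
  tok <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  data.frame(token = tok, pos = as.integer(m), stringsAsFactors = FALSE)
}

gpr_token_type <- function(tok) {
  if (tok == "(") return("lparen")
  if (tok == ")") return("rparen")
  if (toupper(tok) == "AND" || tok %in% c("&", "&&")) return("and")
  if (toupper(tok) == "OR" || tok %in% c("|", "||")) return("or")
  "gene"
}

#' Parse a gene-protein-reaction rule
#'
#' Grammar: `expr := term (OR term)*`, `term := atom (AND atom)*`,
#' `atom := gene | "(" expr ")"`. Operators are case-insensitive; `&`/`|`
#' are accepted synonyms. Malformed expressions raise an error reporting the
#' character position of the offending token.
#'
#' @param text GPR string; `""` yields `NULL` (no rule, reaction always active).
#' @return A GPR abstract syntax tree (nested list), or `NULL`.
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  toks$type <- vapply(toks$token, gpr_token_type, character(1))
  pos <- 1L
  peek <- function() if (pos <= nrow(toks)) toks$type[pos] else "eof"
  fail <- function(what) {
    at <- if (pos <= nrow(toks))
      sprintf("token '%s' at position %d", toks$token[pos], toks$pos[pos])
    else "end of expression"
    stop("GPR parse error in \"", text, "\": expected ", what, ", found ", at,
         call. = FALSE)
  }
  parse_atom <- function() {
    t <- peek()
    if (t == "gene") {
      g <- toks$token[pos]; pos <<- pos + 1L
      return(list(op = "gene", id = g))
    }
    if (t == "lparen") {
      pos <<- pos + 1L
      e <- parse_or()
      if (peek() != "rparen") fail("')'")
      pos <<- pos + 1L
      return(e)
    }
    fail("gene id or '('")
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (peek() == "and") {
      pos <<- pos + 1L
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (peek() == "or") {
      pos <<- pos + 1L
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  ast <- parse_or()
  if (peek() != "eof") fail("end of expression")
  ast
}

#' Evaluate a parsed GPR rule
#'
#' @param ast Result of [parse_gpr()].
#' @param gene_states Named logical vector; genes absent from it are taken as
#'   active (`TRUE`).
#' @return Logical: is the reaction enzymatically supported?
#' @export
eval_gpr <- function(ast, gene_states = logical(0)) {
  if (is.null(ast)) return(TRUE)
  switch(ast$op,
    gene = {
      if (ast$id %in% names(gene_states)) isTRUE(gene_states[[ast$id]]) else TRUE
    },
    and = all(vapply(ast$args, eval_gpr, logical(1), gene_states = gene_states)),
    or  = any(vapply(ast$args, eval_gpr, logical(1), gene_states = gene_states)),
    stop("invalid GPR node"))
}

#' Genes referenced by a parsed GPR rule
#' @param ast Result of [parse_gpr()].
#' @return Character vector of unique gene ids.
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (ast$op == "gene") return(ast$id)
  unique(unlist(lapply(ast$args, gpr_genes)))
}
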