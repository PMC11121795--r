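#' Parse a gene-reaction rule into a boolean syntax tree
#'
#' Accepts the usual COBRA dialect: gene identifiers combined with
#' `and` / `or` (case-insensitive) and parentheses. Returns `NULL` for
#' an empty rule, otherwise a nested list of nodes
#' `list(op = "and"|"or", args = list(...))` with leaves
#' `list(gene = "<id>")`.
#'
#' @param rule gene-reaction rule string.
#' @return parse tree or `NULL`.
#' @export
gpr_parse <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unparseable gene-reaction rule: '", rule, "'")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        stop("unbalanced parentheses in rule: '", rule, "'")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("unparseable gene-reaction rule: '", rule, "'")
    list(gene = t)
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("trailing tokens in gene-reaction rule: '", rule, "'")
  out
}

#' Genes referenced by a rule tree
#' @param ast result of [gpr_parse()].
#' @return character vector of gene ids (unique, in appearance order).
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character())
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Serialize a rule tree back to a rule string
#' @param ast result of [gpr_parse()].
#' @return canonical rule string (`""` for `NULL`).
#' @export
gpr_to_string <- function(ast) {
  if (is.null(ast)) return("")
  rec <- function(node, parent_op) {
    if (!is.null(node$gene)) return(node$gene)
    s <- paste(vapply(node$args, rec, "", node$op),
               collapse = paste0(" ", node$op, " "))
    if (!is.na(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  rec(ast, NA_character_)
}
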