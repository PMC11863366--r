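#' Select atoms with a selection expression
#'
#' Evaluates a compact atom-selection expression against a system and
#' returns the matching atom ids, sorted and duplicate-free. The grammar is
#' a documented subset of the selection languages common in MD analysis
#' tools:
#'
#' * keywords: `name`, `resname`, `element`, `resid`, `index`, `all`
#' * each keyword takes one or more values: `name OW HW1 HW2`
#' * string values may end in a `*` wildcard: `name H*`
#' * `resid`/`index` accept ranges: `resid 5:10` or `resid 5 to 10`
#'   (`index` refers to the atom `id` column)
#' * boolean operators `and`, `or`, `not`, with parentheses; `not` binds
#'   tightest, then `and`, then `or`
#'
#' @param system an `md_system`.
#' @param expression selection string, e.g. `"resname SOL and name OW"`.
#' @return integer vector of atom ids (class `atom_selection`), possibly
#'   empty; the expression is kept in the `"expression"` attribute.
#' @examples
#' sys <- make_fixture("sphere", radius = 8, spacing = 3, box = c(25, 25, 25))
#' length(select_atoms(sys, "all"))
#' @export
select_atoms <- function(system, expression) {
  if (inherits(expression, "atom_selection")) return(expression)
  stopifnot(is.character(expression), length(expression) == 1L)
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ids <- sel_parse_or(st, system)
  if (st$pos <= nrow(st$toks))
    stop_fmt("selection parse error at position %d: unexpected '%s'",
             st$toks$start[st$pos], st$toks$text[st$pos])
  structure(sort(unique(ids)), class = "atom_selection",
            expression = expression)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atoms: \"%s\"\n", length(x),
              attr(x, "expression") %||% ""))
  invisible(x)
}

sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, expr, perl = TRUE)
  if (m[[1]][1] == -1) stop_fmt("empty selection expression")
  data.frame(text = regmatches(expr, m)[[1]], start = as.integer(m[[1]]),
             stringsAsFactors = FALSE)
}

sel_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NA_character_ else st$toks$text[st$pos]
}
sel_take <- function(st) {
  t <- sel_peek(st)
  st$pos <- st$pos + 1L
  t
}
sel_err <- function(st, msg) {
  pos <- if (st$pos > nrow(st$toks)) {
    nchar_end <- st$toks$start[nrow(st$toks)] +
      nchar(st$toks$text[nrow(st$toks)])
    nchar_end
  } else st$toks$start[st$pos]
  stop_fmt("selection parse error at position %d: %s", pos, msg)
}

SEL_KEYWORDS <- c("name", "resname", "element", "resid", "index", "all")
SEL_RESERVED <- c(SEL_KEYWORDS, "and", "or", "not", "(", ")", "to")

sel_parse_or <- function(st, system) {
  ids <- sel_parse_and(st, system)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "or") {
    sel_take(st)
    ids <- union(ids, sel_parse_and(st, system))
  }
  ids
}

sel_parse_and <- function(st, system) {
  ids <- sel_parse_not(st, system)
  while (!is.na(sel_peek(st)) && sel_peek(st) == "and") {
    sel_take(st)
    ids <- intersect(ids, sel_parse_not(st, system))
  }
  ids
}

sel_parse_not <- function(st, system) {
  if (!is.na(sel_peek(st)) && sel_peek(st) == "not") {
    sel_take(st)
    return(setdiff(system$atoms$id, sel_parse_not(st, system)))
  }
  sel_parse_primary(st, system)
}

sel_parse_primary <- function(st, system) {
  t <- sel_peek(st)
  if (is.na(t)) sel_err(st, "expected a keyword or '('")
  if (t == "(") {
    sel_take(st)
    ids <- sel_parse_or(st, system)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      sel_err(st, "expected ')'")
    sel_take(st)
    return(ids)
  }
  if (!t %in% SEL_KEYWORDS)
    sel_err(st, sprintf("unknown keyword '%s'", t))
  sel_take(st)
  if (t == "all") return(system$atoms$id)
  vals <- character(0)
  repeat {
    v <- sel_peek(st)
    if (is.na(v) || v %in% SEL_RESERVED) {
      # allow "5 to 10" ranges for numeric keywords
      if (!is.na(v) && v == "to" && length(vals) &&
          t %in% c("resid", "index")) {
        sel_take(st)
        hi <- sel_take(st)
        if (is.na(hi)) sel_err(st, "expected a number after 'to'")
        vals[length(vals)] <- paste0(vals[length(vals)], ":", hi)
        next
      }
      break
    }
    sel_take(st)
    vals <- c(vals, v)
  }
  if (!length(vals)) sel_err(st, sprintf("keyword '%s' needs a value", t))
  at <- system$atoms
  if (t %in% c("resid", "index")) {
    nums <- unlist(lapply(vals, function(v) {
      if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
        r <- as.integer(strsplit(v, ":")[[1]])
        seq.int(r[1], r[2])
      } else {
        n <- suppressWarnings(as.integer(v))
        if (is.na(n)) sel_err(st, sprintf("'%s' is not a number", v))
        n
      }
    }))
    field <- if (t == "resid") at$resid else at$id
    return(at$id[field %in% nums])
  }
  field <- switch(t, name = at$name, resname = at$resname,
                  element = at$element)
  keep <- rep(FALSE, nrow(at))
  for (v in vals) {
    if (endsWith(v, "*")) {
      keep <- keep | startsWith(field, substr(v, 1, nchar(v) - 1L))
    } else {
      keep <- keep | field == v
    }
  }
  at$id[keep]
}

# resolve a selection argument (string or atom_selection) to atom ids
resolve_selection <- function(system, sel, what = "selection") {
  if (is.null(sel)) stop_fmt("%s must not be NULL", what)
  if (inherits(sel, "atom_selection")) return(as.integer(sel))
  if (is.character(sel)) return(as.integer(select_atoms(system, sel)))
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  stop_fmt("%s must be a string, atom ids or an atom_selection", what)
}
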