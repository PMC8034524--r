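## Serialization and standard-format import/export.  Machines are stored
## in a validatable JSON document:
##
## {
##   "schema_version": "1.0",
##   "alphabets": {"input": [...], "output": [...]},
##   "states": [
##     {"id": "s", "transitions": [
##        {"to": "e", "in": "A", "out": "A", "weight": 1}, ... ]},
##     ...
##   ],
##   "params": {"values": {...}, "prob_groups": [[...]], "rates": [...]}
## }
##
## Absent "in"/"out" fields denote epsilon.  A weight is a number, a
## parameter-name string, or an operator object with exactly one of the
## keys "+", "*", "-", "/", "pow", "exp", "log" mapping to its operand
## array.  Keys are emitted in the canonical order above, so
## write -> read -> write is byte-identical.

WEIGHT_OPS <- c("+", "*", "-", "/", "pow", "exp", "log")

weightToJSONable <- function(e) {
  e <- asWeight(e)
  switch(e$kind,
    const = e$value,
    param = e$name,
    op = setNames(list(lapply(e$args, weightToJSONable)), e$op))
}

parseWeightJSON <- function(x, pointer, errs) {
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x) || x < 0)
      return(list(NULL, c(errs, paste0(pointer,
        ": weight constant must be a finite non-negative number"))))
    return(list(wConst(x), errs))
  }
  if (is.character(x) && length(x) == 1L) return(list(wParam(x), errs))
  if (is.list(x) && length(names(x)) == 1L && names(x) %in% WEIGHT_OPS) {
    op <- names(x)
    operands <- x[[1L]]
    if (!is.list(operands)) operands <- as.list(operands)
    args <- list()
    for (i in seq_along(operands)) {
      r <- parseWeightJSON(operands[[i]],
                           paste0(pointer, "/", op, "/", i - 1L), errs)
      errs <- r[[2L]]
      if (is.null(r[[1L]])) return(list(NULL, errs))
      args[[i]] <- r[[1L]]
    }
    arity <- c("+" = NA, "*" = NA, "-" = 2, "/" = 2, "pow" = 2,
               "exp" = 1, "log" = 1)[[op]]
    if (!is.na(arity) && length(args) != arity)
      return(list(NULL, c(errs, paste0(
        pointer, ": operator '", op, "' takes ", arity, " operand(s)"))))
    if (length(args) == 0L)
      return(list(NULL, c(errs, paste0(pointer, ": empty operand list"))))
    return(list(wOp(op, args), errs))
  }
  list(NULL, c(errs, paste0(
    pointer, ": weight must be a number, a parameter name, or an operator ",
    "object with exactly one of the keys ",
    paste(WEIGHT_OPS, collapse = ", "))))
}

#' Convert a machine to / from its JSON document form
#'
#' `machineToDocument` builds the canonical nested-list form of the JSON
#' machine document; `documentToMachine` parses one (as returned by
#' `jsonlite::fromJSON(..., simplifyVector = FALSE)`), stopping with
#' JSON-pointer-labelled messages on schema violations (see
#' [validateMachineDocument()]).
#'
#' @param m A [Machine].
#' @param doc A nested-list machine document.
#' @return A nested list / a [Machine].
#' @export
machineToDocument <- function(m) {
  tr <- m@transitions
  byState <- split(seq_len(nrow(tr)), factor(tr$from, levels = m@states))
  states <- lapply(m@states, function(s) {
    trs <- lapply(byState[[s]], function(i) {
      o <- list(to = tr$to[i])
      if (!is.na(tr$input[i])) o$`in` <- tr$input[i]
      if (!is.na(tr$output[i])) o$out <- tr$output[i]
      o$weight <- weightToJSONable(tr$weight[[i]])
      o
    })
    list(id = s, transitions = trs)
  })
  p <- m@params
  list(schema_version = "1.0",
       alphabets = list(input = as.list(m@inputAlphabet),
                        output = as.list(m@outputAlphabet)),
       states = states,
       params = list(
         values = as.list(p@values),
         prob_groups = lapply(p@probGroups, as.list),
         rates = as.list(p@rates)))
}

#' Validate a machine JSON document
#'
#' Structural schema check of a parsed machine document.  Every violation
#' is reported with a JSON-pointer path to the offending element.
#'
#' @param doc Nested list, as from `jsonlite::fromJSON(path,
#'   simplifyVector = FALSE)`.
#' @return Character vector of violations (empty if the document is
#'   schema-valid).
#' @export
validateMachineDocument <- function(doc) {
  errs <- character(0)
  bad <- function(ptr, msg) errs <<- c(errs, paste0(ptr, ": ", msg))
  if (!is.list(doc)) return("/: document must be a JSON object")
  if (is.null(doc$schema_version)) bad("/schema_version", "missing")
  chkAlpha <- function(x, ptr) {
    if (is.null(x)) { bad(ptr, "missing"); return(character(0)) }
    syms <- unlist(x)
    if (length(syms) && (!is.character(syms) || any(nchar(syms) != 1L)))
      bad(ptr, "alphabet symbols must be single characters")
    as.character(syms)
  }
  inA <- chkAlpha(doc$alphabets$input, "/alphabets/input")
  outA <- chkAlpha(doc$alphabets$output, "/alphabets/output")
  if (is.null(doc$states) || !length(doc$states)) {
    bad("/states", "at least one state is required")
    return(errs)
  }
  ids <- character(0)
  for (i in seq_along(doc$states)) {
    s <- doc$states[[i]]
    ptr <- paste0("/states/", i - 1L)
    if (is.null(s$id) || !is.character(s$id)) {
      bad(paste0(ptr, "/id"), "missing or not a string")
      next
    }
    ids <- c(ids, s$id)
  }
  if (anyDuplicated(ids)) bad("/states", "duplicate state ids")
  for (i in seq_along(doc$states)) {
    s <- doc$states[[i]]
    trs <- s$transitions
    if (is.null(trs)) next
    for (j in seq_along(trs)) {
      t <- trs[[j]]
      ptr <- paste0("/states/", i - 1L, "/transitions/", j - 1L)
      if (is.null(t$to) || !(t$to %in% ids))
        bad(paste0(ptr, "/to"), "missing or names an undeclared state")
      if (!is.null(t$`in`) && !(t$`in` %in% inA))
        bad(paste0(ptr, "/in"), "symbol not in the input alphabet")
      if (!is.null(t$out) && !(t$out %in% outA))
        bad(paste0(ptr, "/out"), "symbol not in the output alphabet")
      if (is.null(t$weight)) bad(paste0(ptr, "/weight"), "missing")
      else {
        r <- parseWeightJSON(t$weight, paste0(ptr, "/weight"), character(0))
        errs <- c(errs, r[[2L]])
      }
    }
  }
  if (!is.null(doc$params)) {
    v <- doc$params$values
    if (!is.null(v) && length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        bad("/params/values", "values must be a name -> number map")
      else for (nm in names(v))
        if (!is.numeric(v[[nm]]))
          bad(paste0("/params/values/", nm), "must be a number")
    }
  }
  errs
}

#' @rdname machineToDocument
#' @export
documentToMachine <- function(doc) {
  errs <- validateMachineDocument(doc)
  if (length(errs))
    stop("machine document is not schema-valid:\n  ",
         paste(errs, collapse = "\n  "))
  ids <- vapply(doc$states, function(s) s$id, character(1))
  rows <- list()
  for (s in doc$states) for (t in s$transitions) {
    w <- parseWeightJSON(t$weight, "", character(0))[[1L]]
    rows[[length(rows) + 1L]] <- transitionTable(
      s$id, t$to,
      if (is.null(t$`in`)) NA else t$`in`,
      if (is.null(t$out)) NA else t$out,
      list(w))
  }
  p <- doc$params
  pm <- ParamModel(
    values = if (length(p$values)) unlist(p$values) else numeric(0),
    probGroups = lapply(p$prob_groups, function(g) as.character(unlist(g))),
    rates = as.character(unlist(p$rates)))
  Machine(ids, rows,
          as.character(unlist(doc$alphabets$input)),
          as.character(unlist(doc$alphabets$output)),
          pm)
}

#' Read and write machines in the JSON format
#'
#' `writeMachine` serializes in canonical key order (so writing, reading
#' and re-writing a document is byte-identical); `readMachine` parses and
#' schema-validates, reporting violations with JSON-pointer paths.
#'
#' @param m A [Machine].
#' @param path File path; for `writeMachine`, `NULL` returns the JSON
#'   text instead of writing.
#' @return `readMachine`: a [Machine].  `writeMachine`: the JSON text,
#'   invisibly when written to a file.
#' @export
writeMachine <- function(m, path = NULL) {
  doc <- machineToDocument(m)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  json <- paste0(as.character(json), "\n")
  if (is.null(path)) return(json)
  cat(json, file = path)
  invisible(json)
}

#' @rdname writeMachine
#' @export
readMachine <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  documentToMachine(doc)
}

#' Export a machine to GraphViz dot format
#'
#' One node per state (the end state drawn as a double circle), one edge
#' per transition labelled `x/y` with epsilon shown as the conventional
#' glyph; non-unit weights are appended to the label.
#'
#' @param m A [Machine].
#' @return A single string of dot source.
#' @export
exportGraphviz <- function(m) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  lab <- function(s) if (is.na(s)) "ε" else esc(s)
  lines <- c("digraph machine {", "  rankdir=LR;")
  for (s in m@states) {
    shape <- if (s == endState(m)) "doublecircle" else "circle"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", esc(s), shape))
  }
  tr <- m@transitions
  for (i in seq_len(nrow(tr))) {
    w <- tr$weight[[i]]
    wtxt <- if (isConst(w, 1)) "" else paste0(" ", deparseWeight(w))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s/%s%s\"];",
                              esc(tr$from[i]), esc(tr$to[i]),
                              lab(tr$input[i]), lab(tr$output[i]), wtxt))
  }
  paste(c(lines, "}", ""), collapse = "\n")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercased sequences, in file order.
#'   Duplicate record names produce a warning.
#' @export
readFastaSequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- names(set)
  nm <- sub("\\s.*$", "", nm)     # name = first word of the header
  if (anyDuplicated(nm))
    warning("duplicate FASTA record name(s): ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(set)), nm)
}

#' Read a per-position probability matrix from CSV
#'
#' The header row names the symbol columns (e.g. `A,C,G,T,blank` for a CTC
#' recognizer); each subsequent row gives one position's weights, kept in
#' file order.
#'
#' @param path CSV file path.
#' @return Numeric matrix with the header as column names.
#' @export
readProbMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop("non-numeric value at row ", bad[1L], ", column '",
           names(df)[j], "'")
    df[[j]] <- v
  }
  as.matrix(df)
}

hmmerValues <- function(tokens) {
  vapply(tokens, function(t) if (t == "*") Inf else as.numeric(t), numeric(1))
}

#' Import a HMMER3 profile as a generator machine
#'
#' Parses a single-profile HMMER3 text file and builds the standard
#' profile-HMM generator: a begin state, a match/insert/delete block per
#' profile column, and an end state.  Stored values are negative natural
#' logs and convert to weights by `exp(-v)`; `*` denotes infinite cost
#' (weight 0, such transitions are dropped).  Emissions ride on the
#' transitions into each emitting state.
#'
#' @param path Path to a HMMER3 text profile (format `HMMER3/f`).
#' @return A generator [Machine] over the profile's alphabet.
#' @export
readHmmerProfile <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^HMMER3", lines[1L]))
    stop("unsupported format: expected a HMMER3 text profile")
  hmmAt <- grep("^HMM\\s", lines)[1L]
  if (is.na(hmmAt)) stop("no HMM section found")
  syms <- strsplit(trimws(lines[hmmAt]), "\\s+")[[1L]][-1L]
  K <- length(syms)
  i <- hmmAt + 2L                       # skip the transition-name header
  tok <- function(line) strsplit(trimws(line), "\\s+")[[1L]]
  if (grepl("^\\s*COMPO", lines[i])) i <- i + 1L
  ## node 0: insert-0 emissions, then transitions from begin/insert-0
  ins0 <- exp(-hmmerValues(tok(lines[i]))[1:K]); i <- i + 1L
  tr0 <- exp(-hmmerValues(tok(lines[i]))[1:7]); i <- i + 1L
  matchEmit <- list(); insEmit <- list(); trans <- list()
  repeat {
    if (grepl("^//", lines[i])) break
    tks <- tok(lines[i])
    node <- as.integer(tks[1L])
    matchEmit[[node]] <- exp(-hmmerValues(tks[2:(K + 1L)]))
    i <- i + 1L
    insEmit[[node]] <- exp(-hmmerValues(tok(lines[i])[1:K]))
    i <- i + 1L
    trans[[node]] <- exp(-hmmerValues(tok(lines[i])[1:7]))
    i <- i + 1L
  }
  L <- length(matchEmit)
  if (!L) stop("profile has no match columns")
  ## transition order: m->m m->i m->d i->m i->i d->m d->d
  rows <- list()
  add <- function(from, to, emit = NULL, w = 1) {
    if (is.null(emit)) {
      if (w > 0)
        rows[[length(rows) + 1L]] <<- transitionTable(from, to, NA, NA, w)
    } else {
      keep <- which(w * emit > 0)
      if (length(keep))
        rows[[length(rows) + 1L]] <<- transitionTable(
          from, to, NA, syms[keep], as.list(w * emit[keep]))
    }
  }
  Mk <- function(k) paste0("M", k)
  Ik <- function(k) paste0("I", k)
  Dk <- function(k) paste0("D", k)
  add("B", Mk(1), matchEmit[[1]], tr0[1])
  add("B", "I0", ins0, tr0[2])
  add("B", Dk(1), NULL, tr0[3])
  add("I0", Mk(1), matchEmit[[1]], tr0[4])
  add("I0", "I0", ins0, tr0[5])
  for (k in seq_len(L)) {
    tk <- trans[[k]]
    if (k < L) {
      add(Mk(k), Mk(k + 1), matchEmit[[k + 1]], tk[1])
      add(Mk(k), Ik(k), insEmit[[k]], tk[2])
      add(Mk(k), Dk(k + 1), NULL, tk[3])
      add(Ik(k), Mk(k + 1), matchEmit[[k + 1]], tk[4])
      add(Ik(k), Ik(k), insEmit[[k]], tk[5])
      add(Dk(k), Mk(k + 1), matchEmit[[k + 1]], tk[6])
      add(Dk(k), Dk(k + 1), NULL, tk[7])
    } else {
      add(Mk(k), "E", NULL, tk[1])
      add(Mk(k), Ik(k), insEmit[[k]], tk[2])
      add(Ik(k), "E", NULL, tk[4])
      add(Ik(k), Ik(k), insEmit[[k]], tk[5])
      add(Dk(k), "E", NULL, tk[6])
    }
  }
  states <- c("B", "I0",
              as.vector(vapply(seq_len(L), function(k)
                c(Mk(k), Ik(k), Dk(k)), character(3))),
              "E")
  m <- Machine(states, rows, character(0), syms, check = FALSE)
  tidyMachine(m)
}
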