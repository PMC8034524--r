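## Weight expressions: closed-form differentiable expressions over named
## parameters.  Represented as recursive lists with a `kind` field:
##   const -- non-negative numeric constant
##   param -- reference to a named parameter
##   op    -- operator node; op is one of "+", "*", "-", "/", "pow",
##            "exp", "log"; "+" and "*" are n-ary, "-", "/", "pow" binary,
##            "exp" and "log" unary.

#' Weight expression constructors
#'
#' Transition weights are closed-form differentiable expressions over named
#' parameters.  The expression grammar allows non-negative real constants,
#' parameter references, sums, products, differences, quotients, powers,
#' exponentials and natural logarithms.  Bare numerics and single parameter
#' names are accepted wherever a weight expression is expected and coerced
#' with [asWeight()].
#'
#' @param x A numeric constant (`wConst`), parameter name (`wParam`), or any
#'   object coercible to a weight expression (`asWeight`).
#' @param ... Operand expressions (or objects coercible to them).
#' @param a,b Operand expressions.
#' @return A `WeightExpr` object.
#' @examples
#' e <- wProd(0.5, wParam("p"))
#' evaluateWeight(e, c(p = 0.4))
#' @name WeightExpr
NULL

newWeight <- function(x) structure(x, class = "WeightExpr")

#' @rdname WeightExpr
#' @export
wConst <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x >= 0)
  newWeight(list(kind = "const", value = as.numeric(x)))
}

#' @rdname WeightExpr
#' @export
wParam <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  newWeight(list(kind = "param", name = x))
}

wOp <- function(op, args) {
  args <- lapply(args, asWeight)
  newWeight(list(kind = "op", op = op, args = args))
}

#' @rdname WeightExpr
#' @export
wSum <- function(...) wOp("+", list(...))

#' @rdname WeightExpr
#' @export
wProd <- function(...) wOp("*", list(...))

#' @rdname WeightExpr
#' @export
wDiff <- function(a, b) wOp("-", list(a, b))

#' @rdname WeightExpr
#' @export
wQuot <- function(a, b) wOp("/", list(a, b))

#' @rdname WeightExpr
#' @export
wPow <- function(a, b) wOp("pow", list(a, b))

#' @rdname WeightExpr
#' @export
wExp <- function(a) wOp("exp", list(a))

#' @rdname WeightExpr
#' @export
wLog <- function(a) wOp("log", list(a))

#' @rdname WeightExpr
#' @export
asWeight <- function(x) {
  if (inherits(x, "WeightExpr")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(wConst(x))
  if (is.character(x) && length(x) == 1L) return(wParam(x))
  if (is.list(x) && !is.null(x$kind)) return(newWeight(x))
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a weight expression")
}

isConst <- function(e, value = NULL) {
  e$kind == "const" && (is.null(value) || e$value == value)
}

#' Parameter names referenced by a weight expression
#' @param e A `WeightExpr`.
#' @return Character vector of parameter names (possibly empty).
#' @export
weightParams <- function(e) {
  e <- asWeight(e)
  switch(e$kind,
    const = character(0),
    param = e$name,
    op = unique(unlist(lapply(e$args, weightParams))))
}

#' Evaluate a weight expression
#'
#' Evaluates the expression under a full numeric assignment of the
#' parameters it references.  The result must be a finite non-negative real;
#' anything else (including NaN from e.g. log of a negative intermediate) is
#' a domain error.
#'
#' @param e A `WeightExpr` (or coercible object).
#' @param params A named numeric vector or a [ParamModel].
#' @return A single non-negative finite numeric.
#' @export
evaluateWeight <- function(e, params = numeric(0)) {
  e <- asWeight(e)
  vals <- paramValues(params)
  v <- evalWeightRec(e, vals)
  if (!is.finite(v) || v < 0)
    stop("weight evaluates to ", v, ", not a finite non-negative real")
  v
}

paramValues <- function(params) {
  if (is(params, "ParamModel")) params@values
  else if (is.numeric(params)) params
  else stop("params must be a named numeric vector or a ParamModel")
}

evalWeightRec <- function(e, vals) {
  switch(e$kind,
    const = e$value,
    param = {
      if (is.na(match(e$name, names(vals))))
        stop("parameter '", e$name, "' is not assigned a value")
      unname(vals[[e$name]])
    },
    op = {
      a <- vapply(e$args, evalWeightRec, numeric(1), vals = vals)
      switch(e$op,
        "+" = sum(a),
        "*" = prod(a),
        "-" = a[1L] - a[2L],
        "/" = a[1L] / a[2L],
        "pow" = a[1L]^a[2L],
        "exp" = exp(a[1L]),
        "log" = log(a[1L]),
        stop("unknown operator '", e$op, "'"))
    })
}

#' Symbolic derivative of a weight expression
#'
#' Differentiates the expression tree with respect to one named parameter.
#' The derivative is itself a weight expression (it may evaluate to a
#' negative number, e.g. for differences); constant subtrees are folded.
#'
#' @param e A `WeightExpr`.
#' @param name Parameter name to differentiate with respect to.
#' @return A `WeightExpr` for the partial derivative.
#' @export
differentiateWeight <- function(e, name) {
  e <- asWeight(e)
  simplifyWeight(diffRec(e, name))
}

diffRec <- function(e, name) {
  switch(e$kind,
    const = wConst(0),
    param = if (identical(e$name, name)) wConst(1) else wConst(0),
    op = {
      a <- e$args
      d <- lapply(a, diffRec, name = name)
      switch(e$op,
        "+" = wOp("+", d),
        "*" = {
          # product rule, n-ary
          terms <- lapply(seq_along(a), function(i) {
            wOp("*", c(d[i], a[-i]))
          })
          wOp("+", terms)
        },
        "-" = wDiff(d[[1L]], d[[2L]]),
        "/" = wQuot(wDiff(wProd(d[[1L]], a[[2L]]), wProd(a[[1L]], d[[2L]])),
                    wPow(a[[2L]], wConst(2))),
        "pow" = {
          # d(u^v) = u^v * (v' log u + v u'/u)
          wProd(newWeight(e),
                wSum(wProd(d[[2L]], wLog(a[[1L]])),
                     wQuot(wProd(a[[2L]], d[[1L]]), a[[1L]])))
        },
        "exp" = wProd(wExp(a[[1L]]), d[[1L]]),
        "log" = wQuot(d[[1L]], a[[1L]]))
    })
}

## Fold constants and drop algebraic units; keeps derivative trees small.
simplifyWeight <- function(e) {
  if (e$kind != "op") return(e)
  args <- lapply(e$args, simplifyWeight)
  allConst <- all(vapply(args, function(a) a$kind == "const", logical(1)))
  if (allConst && !(e$op %in% c("-", "/", "log"))) {
    # safe to fold ops that stay non-negative on non-negative constants
    v <- evalWeightRec(list(kind = "op", op = e$op, args = args), numeric(0))
    if (is.finite(v) && v >= 0) return(wConst(v))
  }
  if (e$op == "+") {
    args <- Filter(function(a) !isConst(a, 0), args)
    if (length(args) == 0L) return(wConst(0))
    if (length(args) == 1L) return(args[[1L]])
  }
  if (e$op == "*") {
    if (any(vapply(args, isConst, logical(1), value = 0))) return(wConst(0))
    args <- Filter(function(a) !isConst(a, 1), args)
    if (length(args) == 0L) return(wConst(1))
    if (length(args) == 1L) return(args[[1L]])
  }
  if (e$op == "-" && isConst(args[[2L]], 0)) return(args[[1L]])
  if (e$op == "/" && isConst(args[[2L]], 1)) return(args[[1L]])
  if (e$op == "pow" && isConst(args[[2L]], 1)) return(args[[1L]])
  newWeight(list(kind = "op", op = e$op, args = args))
}

#' @export
print.WeightExpr <- function(x, ...) {
  cat(deparseWeight(x), "\n")
  invisible(x)
}

deparseWeight <- function(e) {
  e <- asWeight(e)
  switch(e$kind,
    const = format(e$value),
    param = e$name,
    op = {
      a <- vapply(e$args, deparseWeight, character(1))
      switch(e$op,
        "+" = paste0("(", paste(a, collapse = " + "), ")"),
        "*" = paste0("(", paste(a, collapse = " * "), ")"),
        "-" = paste0("(", a[1L], " - ", a[2L], ")"),
        "/" = paste0("(", a[1L], " / ", a[2L], ")"),
        "pow" = paste0(a[1L], "^", a[2L]),
        "exp" = paste0("exp(", a[1L], ")"),
        "log" = paste0("log(", a[1L], ")"))
    })
}

## Decompose a weight into monomial form c * prod(param_i ^ k_i), or NULL if
## the expression is not a monomial.  Used by the EM M-step, which is
## closed-form only for monomial weights.
asMonomial <- function(e) {
  e <- asWeight(e)
  switch(e$kind,
    const = list(coef = e$value, powers = numeric(0)),
    param = list(coef = 1, powers = stats::setNames(1, e$name)),
    op = {
      if (e$op == "*") {
        parts <- lapply(e$args, asMonomial)
        if (any(vapply(parts, is.null, logical(1)))) return(NULL)
        powers <- numeric(0)
        coef <- 1
        for (p in parts) {
          coef <- coef * p$coef
          for (nm in names(p$powers)) {
            powers[nm] <- (if (nm %in% names(powers)) powers[[nm]] else 0) +
              p$powers[[nm]]
          }
        }
        list(coef = coef, powers = powers)
      } else if (e$op == "pow" && e$args[[1L]]$kind == "param" &&
                 e$args[[2L]]$kind == "const") {
        list(coef = 1,
             powers = stats::setNames(e$args[[2L]]$value, e$args[[1L]]$name))
      } else NULL
    })
}
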