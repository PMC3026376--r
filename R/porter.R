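#' Porter stem of a single word
#'
#' The original Porter (1980) suffix-stripping algorithm, used by the
#' hypothesis-term search to match free-text hypothesis terms against GO term
#' names, synonyms and definitions (e.g. both "inflammation" and
#' "inflammatory" reduce to stems beginning "inflamm", so a hypothesis term
#' "inflammation" finds the GO term "inflammatory response" by substring
#' match). Input is lowercased; words shorter than three letters are returned
#' unchanged, as the algorithm specifies.
#'
#' @param word a single word (character scalar).
#' @return the stem (character scalar).
#' @examples
#' porter_stem("apoptosis")       # "apoptosi"
#' porter_stem("inflammation")    # "inflamm"
#' porter_stem("generalizations") # "gener"
#' @export
porter_stem <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  w <- tolower(word)
  if (nchar(w) < 3L) return(w)

  is_cons <- function(chs, i) {
    ch <- chs[[i]]
    if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
    if (ch == "y") return(if (i == 1L) TRUE else !is_cons(chs, i - 1L))
    TRUE
  }
  measure <- function(stem) {
    chs <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (!length(chs)) return(0L)
    flags <- vapply(seq_along(chs), function(i) is_cons(chs, i), logical(1))
    # count V-to-C transitions after the optional initial C run
    m <- 0L
    prev_vowel <- FALSE
    for (f in flags) {
      if (f && prev_vowel) m <- m + 1L
      prev_vowel <- !f
    }
    m
  }
  has_vowel <- function(stem) {
    chs <- strsplit(stem, "", fixed = TRUE)[[1]]
    if (!length(chs)) return(FALSE)
    any(!vapply(seq_along(chs), function(i) is_cons(chs, i), logical(1)))
  }
  ends_double_cons <- function(s) {
    n <- nchar(s)
    if (n < 2L) return(FALSE)
    chs <- strsplit(s, "", fixed = TRUE)[[1]]
    chs[[n]] == chs[[n - 1L]] && is_cons(chs, n)
  }
  ends_cvc <- function(s) {
    n <- nchar(s)
    if (n < 3L) return(FALSE)
    chs <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!is_cons(chs, n) || is_cons(chs, n - 1L) || !is_cons(chs, n - 2L))
      return(FALSE)
    !(chs[[n]] %in% c("w", "x", "y"))
  }
  ends_with <- function(s, suf) {
    nchar(s) >= nchar(suf) &&
      substring(s, nchar(s) - nchar(suf) + 1L) == suf
  }
  chop <- function(s, suf) substring(s, 1L, nchar(s) - nchar(suf))

  ## Step 1a
  if (ends_with(w, "sses")) w <- chop(w, "es")
  else if (ends_with(w, "ies")) w <- paste0(chop(w, "ies"), "i")
  else if (ends_with(w, "ss")) w <- w
  else if (ends_with(w, "s")) w <- chop(w, "s")

  ## Step 1b
  step1b_extra <- FALSE
  if (ends_with(w, "eed")) {
    if (measure(chop(w, "eed")) > 0L) w <- chop(w, "d")
  } else if (ends_with(w, "ed") && has_vowel(chop(w, "ed"))) {
    w <- chop(w, "ed"); step1b_extra <- TRUE
  } else if (ends_with(w, "ing") && has_vowel(chop(w, "ing"))) {
    w <- chop(w, "ing"); step1b_extra <- TRUE
  }
  if (step1b_extra) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (ends_double_cons(w) &&
               !ends_with(w, "l") && !ends_with(w, "s") && !ends_with(w, "z")) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (measure(w) == 1L && ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  ## Step 1c
  if (ends_with(w, "y") && has_vowel(chop(w, "y")))
    w <- paste0(chop(w, "y"), "i")

  apply_rules <- function(w, rules, cond) {
    # rules: list of c(suffix, replacement); longest matching suffix wins,
    # and if its condition fails no shorter suffix is tried (per Porter).
    best <- NULL
    for (r in rules)
      if (ends_with(w, r[[1]]) &&
          (is.null(best) || nchar(r[[1]]) > nchar(best[[1]])))
        best <- r
    if (is.null(best)) return(w)
    stem <- chop(w, best[[1]])
    if (cond(stem, best[[1]])) paste0(stem, best[[2]]) else w
  }

  ## Step 2 (m > 0)
  w <- apply_rules(w, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"),
    c("alli", "al"), c("entli", "ent"), c("eli", "e"), c("ousli", "ous"),
    c("ization", "ize"), c("ation", "ate"), c("ator", "ate"),
    c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"),
    c("biliti", "ble")),
    function(stem, suf) measure(stem) > 0L)

  ## Step 3 (m > 0)
  w <- apply_rules(w, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")),
    function(stem, suf) measure(stem) > 0L)

  ## Step 4 (m > 1; "ion" additionally requires the stem to end in s or t)
  w <- apply_rules(w, list(
    c("al", ""), c("ance", ""), c("ence", ""), c("er", ""), c("ic", ""),
    c("able", ""), c("ible", ""), c("ant", ""), c("ement", ""),
    c("ment", ""), c("ent", ""), c("ion", ""), c("ou", ""), c("ism", ""),
    c("ate", ""), c("iti", ""), c("ous", ""), c("ive", ""), c("ize", "")),
    function(stem, suf) {
      ok <- measure(stem) > 1L
      if (suf == "ion")
        ok <- ok && (ends_with(stem, "s") || ends_with(stem, "t"))
      ok
    })

  ## Step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, "e")
    m <- measure(stem)
    if (m > 1L || (m == 1L && !ends_cvc(stem))) w <- stem
  }
  ## Step 5b
  if (measure(w) > 1L && ends_double_cons(w) && ends_with(w, "l"))
    w <- substring(w, 1L, nchar(w) - 1L)

  w
}
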