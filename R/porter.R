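#' Porter stemming
#'
#' Classic suffix-stripping stemmer for English (Porter, 1980), used to
#' compare biomedical term tokens up to inflection ("receptors" and
#' "receptor" stem identically). Tokens of two characters or fewer, and
#' tokens containing non-alphabetic characters (digits, hyphens), are
#' returned unchanged.
#'
#' @param words Character vector of single tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("receptors", "lymphocytes", "caresses"))
#' @export
porter_stem <- function(words) {
  vapply(as.character(words), .porter_word, character(1), USE.NAMES = FALSE)
}

# consonant test: a,e,i,o,u are vowels; y is a vowel iff preceded by a
# consonant (so "dy" has a vowel, "yoke" starts with a consonant)
.pt_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_cons(chars, i - 1L))
  }
  TRUE
}

# measure m: number of vowel-consonant alternations in [C](VC)^m[V]
.pt_m <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!length(chars)) return(0L)
  types <- vapply(seq_along(chars), function(i) .pt_cons(chars, i), logical(1))
  r <- rle(types)$values
  if (length(r) < 2L) return(0L)
  sum(!r[-length(r)] & r[-1])
}

.pt_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!length(chars)) return(FALSE)
  any(!vapply(seq_along(chars), function(i) .pt_cons(chars, i), logical(1)))
}

.pt_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  .pt_cons(chars, n)
}

# *o: stem ends consonant-vowel-consonant where the final consonant is not
# w, x or y ("hop", "fil"); triggers restoration of a final e
.pt_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  last <- chars[n]
  .pt_cons(chars, n - 2L) && !.pt_cons(chars, n - 1L) && .pt_cons(chars, n) &&
    !(last %in% c("w", "x", "y"))
}

.pt_ends <- function(w, sfx) {
  n <- nchar(w); k <- nchar(sfx)
  n > k && substr(w, n - k + 1L, n) == sfx
}

# apply the first (longest) matching suffix rule; a matched suffix whose
# measure condition fails still terminates the step (Porter's semantics)
.pt_rule_step <- function(w, suffixes, repls, min_m) {
  for (i in seq_along(suffixes)) {
    if (.pt_ends(w, suffixes[i])) {
      stem <- substr(w, 1L, nchar(w) - nchar(suffixes[i]))
      if (.pt_m(stem) > min_m) w <- paste0(stem, repls[i])
      return(w)
    }
  }
  w
}

.pt_step2_sfx <- c("ational", "ization", "iveness", "fulness", "ousness",
                   "tional", "biliti", "entli", "ousli", "alism", "aliti",
                   "iviti", "ation", "ator", "enci", "anci", "izer", "abli",
                   "alli", "eli")
.pt_step2_rep <- c("ate", "ize", "ive", "ful", "ous",
                   "tion", "ble", "ent", "ous", "al", "al",
                   "ive", "ate", "ate", "ence", "ance", "ize", "able",
                   "al", "e")
.pt_step3_sfx <- c("icate", "ative", "alize", "iciti", "ical", "ful", "ness")
.pt_step3_rep <- c("ic", "", "al", "ic", "ic", "", "")
.pt_step4_sfx <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                   "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
                   "al", "er", "ic", "ou")

.porter_word <- function(w) {
  w <- tolower(w)
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  # step 1a: plurals
  if (.pt_ends(w, "sses")) {
    w <- substr(w, 1L, nchar(w) - 2L)
  } else if (.pt_ends(w, "ies")) {
    w <- paste0(substr(w, 1L, nchar(w) - 3L), "i")
  } else if (!.pt_ends(w, "ss") && .pt_ends(w, "s")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  # step 1b: -eed / -ed / -ing
  stripped <- FALSE
  if (.pt_ends(w, "eed")) {
    stem <- substr(w, 1L, nchar(w) - 3L)
    if (.pt_m(stem) > 0L) w <- paste0(stem, "ee")
  } else if (.pt_ends(w, "ed")) {
    stem <- substr(w, 1L, nchar(w) - 2L)
    if (.pt_has_vowel(stem)) { w <- stem; stripped <- TRUE }
  } else if (.pt_ends(w, "ing")) {
    stem <- substr(w, 1L, nchar(w) - 3L)
    if (.pt_has_vowel(stem)) { w <- stem; stripped <- TRUE }
  }
  if (stripped) {
    if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pt_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.pt_m(w) == 1L && .pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i after a vowel
  if (.pt_ends(w, "y") && .pt_has_vowel(substr(w, 1L, nchar(w) - 1L))) {
    w <- paste0(substr(w, 1L, nchar(w) - 1L), "i")
  }

  w <- .pt_rule_step(w, .pt_step2_sfx, .pt_step2_rep, 0L)
  w <- .pt_rule_step(w, .pt_step3_sfx, .pt_step3_rep, 0L)

  # step 4: drop derivational suffixes on long stems; -ion only after s/t
  for (sfx in .pt_step4_sfx) {
    if (.pt_ends(w, sfx)) {
      stem <- substr(w, 1L, nchar(w) - nchar(sfx))
      ok <- .pt_m(stem) > 1L
      if (sfx == "ion") {
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop final e
  if (.pt_ends(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l on long stems
  if (.pt_m(w) > 1L && .pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}
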