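---
title: "Exact solutions of dividing-by-a-half recurrences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact solutions of dividing-by-a-half recurrences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfrec)
```

## The problem

This package solves, exactly and in closed form, the recurrence class

$$x_n = a\,x_{\lceil n/2\rceil} + a\,x_{\lfloor n/2\rfloor}
      + P(\lceil n/2\rceil, \lfloor n/2\rfloor), \qquad n \ge 2,$$

for a nonzero real coefficient $a$ and a bivariate polynomial toll
$P(x,y)=\sum_{r,t} b_{r,t}x^r y^t$, with arbitrary initial value $x_1$.
The class covers the cost recurrences of balanced divide-and-conquer
algorithms and — the application built into this package — the recurrences
satisfied by phylogenetic balance indices on maximally balanced trees
$B_n$, whose values are required to normalize an index to $[0,1]$ for each
leaf count.

The solution is *finite*: it is expressed through the binary decomposition
$n=\sum_{j=1}^{s_n} 2^{q_j(n)}$ (bit positions $q_1<\dots<q_{s_n}$, suffix
sums $M_i=\sum_{j\ge i}2^{q_j}$, with the conventions $q_0=0$, $M_0=n+1$,
$M_{s+1}=0$), the Bernoulli numbers $B_m$ of the first kind, and the sums
$T(d,n,x)=\sum_{k=0}^{n-1}k^d x^k$.  Every index in every sum is bounded by
$\lfloor\log_2 n\rfloor$ and $\deg P$, so the cost of an evaluation grows
logarithmically in $n$.

## Structure of the solution

Linearity splits the problem into monomial tolls: with
$x_n^{(r,t)}(a)$ the solution for toll
$\lceil n/2\rceil^r\lfloor n/2\rfloor^t$ and $x_1=0$,

$$x_n \;=\; \sum_{r,t} b_{r,t}\,x_n^{(r,t)}(a)
 \;+\; \bigl((2a)^{q_s} + (2a-1)(n a^{q_s}-(2a)^{q_s})\bigr)x_1 ,$$

where the last block is the homogeneous solution
(`homogeneous_term()`).  Each $x_n^{(r,t)}(a)$ is assembled from four parts
(`x_monomial()`):

* a polynomial part $\sum_k c_k n^k$ whose coefficients combine binomials
  with Bernoulli numbers and denominators $i\,(2^{i-1}-a)$;
* a "peak sum" part proportional to
  $T(0,q_s,2a) + n a^{q_s} - (2a)^{q_s}$, the closed form of
  $\sum_{k<n} a^{q_{s_k}(k)}$;
* a combination of auxiliary sums $\alpha_n^{(0,i)}(a)$, $i < r+t$;
* when $a = 2^{t+\ell}$ for some $\ell\in\{0,\dots,r-1\}$, an extra block
  with $T(1,q_s,2a)$ and the sums $\alpha_n^{(1,i)}(a)$.

The $\alpha$ sums themselves (`alpha_sum()`) are the accumulated inner sums
$\alpha_n^{(d,m)} = \sum_{k<n} S_k^{(d,m)}$ with
$S_k^{(d,m)} = \sum_{j<s_k} q_j^d (2^{-m}a)^{q_j} M_{j+1}^m$, and have a
Bernoulli/T closed form of the same finite shape.

### The case dispatch

The formula's denominators $2^{i-1}-a$ and $2^{t+l}-a$ vanish exactly when
$a$ is one of finitely many powers of two, and the formula handles this by
*excluding* the offending index and adding the $\ell$-block above.  The
package resolves this bookkeeping in `case_profile()`: $\ell_{a,t} =
\log_2(a) - t$ is defined only when $a$ is an exact power of two (undefined
for $a \le 0$), the flag $\delta_\ell$ is set when $r>0$ and
$\ell\in\{0,\dots,r-1\}$, and one of nine case labels (`a`, `b1`–`b4`,
`c1`–`c4`) is attached.  Two implementation rules make the general formula
total:

1. a summand whose binomial prefactor is zero is skipped *before* its
   denominator is formed (this covers $a = 2^c$ with $c < t$, where the
   singular index always carries a vanishing binomial);
2. the index exclusions are active exactly when $\delta_\ell = 1$ — whenever
   a singular index actually falls inside a summation range, $\delta_\ell$
   is 1, so no division by zero can occur.

Besides the general formula, all nine algebraic specializations are
implemented verbatim (`x_monomial(..., method = "cased")`) and the two are
asserted equal on the full validation grid.

## Why exact rational arithmetic

The dispatch tests exact equalities such as $a = 2^{t+\ell}$, which are
ill-posed in floating point, and the values themselves overflow doubles (at
$n = 2^{12}$, $r+t = 6$, $a = 8$ the solution is of order $2^{72}$).  All
core arithmetic is therefore exact rational, implemented in a small
arbitrary-precision integer/rational kernel under `src/` (base-$2^{32}$
limbs, schoolbook algorithms — ample for the $\sim$40-digit numbers that
occur).  The R surface carries values as canonical `"p/q"` strings wrapped
in a `rational` S3 class with exact `Ops` methods.

Two global conventions matter and are applied everywhere: $0^0 = 1$
(entering through $k=0$ terms of $T$, through $q_1 = 0$ with $d$th powers,
and through $M_{s+1}^0$), and $M_{s+1} = 0$ for the out-of-range suffix sum
(the unique value consistent with the telescoping manipulations the closed
forms rely on).  Doubles supplied as parameters are converted *verbatim* at
their exact binary value — every double is dyadic — so `0.1` is **not**
`1/10`; the documentation tells users to write `"1/10"` when that is meant.
Indices `n` are accepted up to $2^{53}$ (the exactness limit of R numerics);
the solution *values* are unbounded.

## Validation design: two independent paths for everything

The package's central correctness instrument is a pair of code paths for
every quantity, diffed exactly:

* `solve_recurrence(..., method = "oracle")` evaluates the recurrence by
  memoized direct recursion on the two halves — ground truth for the solver;
* `alpha_sum`/`gamma_sum` with `method = "bruteforce"` evaluate the literal
  double sums — ground truth for the closed forms;
* the named sequences add *definitional* evaluators that never touch the
  recurrence: direct bitwise loops for the AND/XOR/OR convolution sums, the
  digit-wise formula `monroe_job()` for the alternating-toll sequence, the
  incremental digit-sum accumulation for A005536, and explicit tree
  construction plus index computation for the four balance-index sequences;
* the tree layer duplicates its own evaluators: the Total Cophenetic index
  via node sums and via literal pairwise LCA depths, the rooted Quartet
  index via node sums and via enumeration of all $\binom{n}{4}$ quadruples.

The validation grid for the solver runs over $n \le 512$, all
$(r,t)\in\{0,\dots,3\}^2$, twelve coefficients
$a \in \{1,-1,2,-2,4,8,\tfrac12,-\tfrac12,3,\tfrac13,\tfrac32,5\}$ and
random rational initial values.  The coefficient set is chosen to hit every
case of the dispatch: both $a=\tfrac12$ branches, $a=1$, powers of two with
$\ell$ in and out of range, negatives (where $\ell$ is undefined), and
non-dyadic rationals.  The grid sizes are the package's validation targets;
they run in a single C++ pass (about 100k exact comparisons in ~15 s).
Smaller ranges ($n \le 128$) are used in the routine unit tests, the full
grid in the acceptance suite.

## The applications layer

**Named sequences.**  Each registered sequence (see `named_sequences()`)
carries its closed form, its recurrence specification, and optionally a
definitional evaluator; `cross_validate()` fills all columns and reports
exact agreement.  Definitional evaluators costing $O(n)$ per term (bitwise
loops, tree constructions) are capped by default at $n \le 256$ inside
`cross_validate()`; the cheap ones run over the full range.  Two
interchange helpers cover common sequence sources: `toll_from_univariate()`
expands a toll given as a polynomial in $n$ via
$n = \lceil n/2\rceil + \lfloor n/2\rfloor$; `stephan_spec()` converts an
even/odd interleaved pair
$a_{2n} = C a_n + C a_{n-1} + P(n)$, $a_{2n+1} = 2C a_n + Q(n)$ into the
half-recurrence satisfied by $x_n = a_{n-1}$; `alternating_toll()` rewrites
$(-1)^n$ factors through $(-1)^n = 1 - 2(\lceil n/2\rceil-\lfloor
n/2\rfloor)$.  OEIS identifiers are labels only — validation is internal,
never against fetched data.

**Trees.**  Newick I/O is delegated to ape behind validating wrappers;
index computations walk the edge matrix directly and treat child order as
irrelevant.  Two conventions were genuinely open and are fixed as follows:

* *Total Cophenetic index*: implemented as the sum over pairs of **leaves**
  of the depth of their lowest common ancestor.  This is the definition
  consistent with the recurrence toll
  $\binom{\lceil n/2\rceil}{2}+\binom{\lfloor n/2\rfloor}{2}$ that the
  closed form solves (the tests assert that the tree computation on $B_n$
  reproduces the closed form exactly); descriptions of the index as a sum
  over internal-node pairs appear in the literature but do not match that
  recurrence.
* *Normalization orientation*: `normalize_index()` returns
  $(I - \min)/(\max - \min)$ for Sackin, Colless and Total Cophenetic, and
  the inverted $(\max - I)/(\max - \min)$ for the rooted Quartet index, so
  **0 always means maximally balanced and 1 the caterpillar**, for all four
  indices.  The rescaling to $[0,1]$ is standard; the direction is a package
  convention, stated here and in the function documentation.

The balanced-tree side of the extremes comes from the closed forms
(`sackin_min()`, `colless_min()`, `cophenetic_min()`, `quartet_max()`); the
caterpillar side is computed directly on the constructed caterpillar, which
is cheap and avoids importing further closed formulas.  Multifurcating
inputs get Sackin and Total Cophenetic values (their definitions need no
bifurcation) while Colless and Quartet raise an error rather than silently
generalizing.  A single leaf ($n = 1$) is represented by a degenerate
one-tip structure with all indices 0; it cannot be written to Newick.

## Degenerate inputs and edge policies

* $n = 1$ returns $x_1$ directly (the closed formula is stated for
  $n \ge 2$; the monomial solutions vanish at 1 by construction).
* $a = 0$ is rejected everywhere; a toll with no terms gives the pure
  homogeneous solution.
* `gamma_sum()`'s closed form requires $p < m$ and rejects other input; the
  brute-force method accepts any indices.  The closed form of
  `alpha_sum()` is stated for $d \in \{0,1\}$ and rejects larger $d$; the
  brute force again accepts any $d$.
* The inner-sum ranges of the $S$ and $\gamma$ sums differ by one term
  ($j \le s_k - 1$ versus $i \le s_k$); both are encoded explicitly since
  with $0^0 = 1$ the difference is silent except at $p = 0$.
* `vanishing_check()` decides membership of the toll in the ideal
  $(x-y)(x-y-1)\,\mathbb{Q}[x,y]$ through the coefficient identities that
  characterize $P(x,x)=P(x,x-1)=0$; such tolls provably yield the
  identically-zero solution with $x_1=0$, which the tests confirm to
  $n \le 200$.

## Known limitations

* Unequal coefficients on the ceiling and floor terms are out of scope, as
  are non-polynomial tolls (rational functions, $(-1)^{\lfloor n/2\rfloor}$
  factors) and irrational $a$ beyond exact conversion of the supplied
  binary double.
* Asymptotic (Master-Theorem) classification is not computed; the package
  produces exact values, from which growth behaviour can be inspected
  empirically.
* The tree layer targets rooted trees; unrooted trees and branch-length
  aware indices are out of scope.
* Performance: evaluation is logarithmic in $n$, but the rational kernel is
  schoolbook; tolls of very high degree (say beyond 10) would profit from
  asymptotically faster integer arithmetic.
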