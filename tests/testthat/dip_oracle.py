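"""Brute-force dip oracle.

For each sample, the dip (minimal sup-distance between the empirical CDF
and any unimodal CDF) is found by exact linear programming: for every
admissible mode position (between two distinct values, or an atom at a
value), minimize the band half-width rho subject to a convex nondecreasing
rising flank, a concave nondecreasing falling flank, band constraints and
monotone coupling at the mode. The dip is the minimum over mode positions.

Reads a JSON list of samples on stdin, writes a JSON list of dips.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_split(w, lo_b, hi_b, pi, si, relax_last_l, relax_first_u):
    np_, ns = len(pi), len(si)
    nv = 1 + np_ + ns  # rho, g..., h...
    A_ub, b_ub = [], []

    def row(entries):
        r = np.zeros(nv)
        for idx, val in entries:
            r[idx] += val
        return r

    gi = lambda j: 1 + j
    hi = lambda j: 1 + np_ + j
    for j, i in enumerate(pi):
        A_ub.append(row([(gi(j), 1), (0, -1)])); b_ub.append(hi_b[i])
        if not (relax_last_l and j == np_ - 1):
            A_ub.append(row([(gi(j), -1), (0, -1)])); b_ub.append(-lo_b[i])
    for j, i in enumerate(si):
        if not (relax_first_u and j == 0):
            A_ub.append(row([(hi(j), 1), (0, -1)])); b_ub.append(hi_b[i])
        A_ub.append(row([(hi(j), 1)])); b_ub.append(1.0)
        A_ub.append(row([(hi(j), -1), (0, -1)])); b_ub.append(-lo_b[i])
    if np_ >= 2:
        A_ub.append(row([(gi(0), 1), (gi(1), -1)])); b_ub.append(0.0)
        for j in range(np_ - 2):
            d1 = w[pi[j + 1]] - w[pi[j]]
            d2 = w[pi[j + 2]] - w[pi[j + 1]]
            A_ub.append(row([(gi(j + 2), -1 / d2),
                             (gi(j + 1), 1 / d2 + 1 / d1),
                             (gi(j), -1 / d1)]))
            b_ub.append(0.0)
    if ns >= 2:
        A_ub.append(row([(hi(ns - 1), -1), (hi(ns - 2), 1)])); b_ub.append(0.0)
        for j in range(ns - 2):
            d1 = w[si[j + 1]] - w[si[j]]
            d2 = w[si[j + 2]] - w[si[j + 1]]
            A_ub.append(row([(hi(j + 2), 1 / d2),
                             (hi(j + 1), -1 / d2 - 1 / d1),
                             (hi(j), 1 / d1)]))
            b_ub.append(0.0)
    if np_ >= 1 and ns >= 1:
        A_ub.append(row([(gi(np_ - 1), 1), (hi(0), -1)])); b_ub.append(0.0)
    c = np.zeros(nv)
    c[0] = 1.0
    res = linprog(c, A_ub=np.array(A_ub), b_ub=np.array(b_ub),
                  bounds=[(0, None)] * nv, method="highs")
    return res.fun if res.status == 0 else np.inf


def dip_oracle(x):
    sx = np.sort(np.asarray(x, dtype=float))
    n = len(sx)
    w, counts = np.unique(sx, return_counts=True)
    K = len(w)
    cum = np.cumsum(counts)
    lo_b = cum / n
    hi_b = np.concatenate([[0.0], cum[:-1]]) / n
    best = np.inf
    for k in range(K + 1):  # mode in gap after k knots
        pi = list(range(k))
        si = list(range(k, K))
        best = min(best, solve_split(w, lo_b, hi_b, pi, si, False, False))
    for m in range(K):      # atom at knot m
        best = min(best, solve_split(w, lo_b, hi_b, list(range(m + 1)),
                                     list(range(m, K)), True, True))
    return float(best)


def main():
    samples = json.load(sys.stdin)
    json.dump([dip_oracle(s) for s in samples], sys.stdout)


if __name__ == "__main__":
    main()
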