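#!/usr/bin/env python
"""Independent dense-matrix Markov clustering reference.

Reads JSON from stdin: a list of problems, each
  {"n": int, "edges": [[i, j, w], ...], "inflation": float,
   "expansion": int, "prune": float, "tol": float, "max_iter": int}
with 1-based node indices, and writes a JSON list of partitions, each a
list of clusters (sorted lists of 1-based node indices), clusters sorted
by decreasing size then smallest member.
"""
import json
import sys

import numpy as np


def mcl(n, edges, inflation=2.0, expansion=2, prune=1e-5, tol=1e-8,
        max_iter=100):
    M = np.zeros((n, n))
    for i, j, w in edges:
        M[i - 1, j - 1] = w
        M[j - 1, i - 1] = w
    # self loops: max incident weight, 1 for isolated nodes
    mx = M.max(axis=0)
    mx[mx == 0] = 1.0
    np.fill_diagonal(M, mx)

    def colnorm(A):
        s = A.sum(axis=0)
        zero = s == 0
        if zero.any():
            idx = np.where(zero)[0]
            A[idx, idx] = 1.0
            s = A.sum(axis=0)
        return A / s

    M = colnorm(M)
    for _ in range(max_iter):
        E = M.copy()
        for _ in range(expansion - 1):
            E = E @ M
        E = E ** inflation
        E = colnorm(E)
        E[E < prune] = 0.0
        E = colnorm(E)
        delta = np.abs(E - M).max()
        M = E
        if delta < tol:
            break

    d = np.diag(M)
    att = np.where(d > 0)[0]
    if att.size == 0:
        att = np.arange(n)
    # attractor systems: connected components of mutual support
    A = (M[np.ix_(att, att)] + M[np.ix_(att, att)].T) > 0
    comp = -np.ones(att.size, dtype=int)
    cid = 0
    for s in range(att.size):
        if comp[s] >= 0:
            continue
        stack = [s]
        comp[s] = cid
        while stack:
            v = stack.pop(0)
            for u in np.where(A[v] & (comp < 0))[0]:
                comp[u] = cid
                stack.append(u)
        cid += 1
    nsys = cid
    flow = np.zeros((nsys, n))
    for s in range(nsys):
        flow[s] = M[att[comp == s]].sum(axis=0)
    # lexicographic tie-break on the smallest member node index
    sys_min = [att[comp == s].min() for s in range(nsys)]
    clusters = [[] for _ in range(nsys)]
    singletons = []
    for j in range(n):
        f = flow[:, j]
        if f.max() == 0:
            singletons.append([j + 1])
            continue
        best = np.where(f == f.max())[0]
        if best.size > 1:
            best = sorted(best, key=lambda s: sys_min[s])
        clusters[int(best[0])].append(j + 1)
    out = [sorted(c) for c in clusters if c] + singletons
    out.sort(key=lambda c: (-len(c), c[0]))
    return out


def main():
    problems = json.load(sys.stdin)
    results = []
    for p in problems:
        results.append(mcl(p["n"], p.get("edges", []),
                           p.get("inflation", 2.0), p.get("expansion", 2),
                           p.get("prune", 1e-5), p.get("tol", 1e-8),
                           p.get("max_iter", 100)))
    json.dump(results, sys.stdout)


if __name__ == "__main__":
    main()
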