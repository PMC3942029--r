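#!/usr/bin/env python
"""Independent reference implementation of Markov clustering.

Reads a weighted edge list (node_a<TAB>node_b<TAB>weight, with header),
runs MCL with the documented conventions (self-loops = max incident
weight, column-stochastic transition matrix, expansion by squaring,
entrywise inflation with column renormalization, pruning, convergence on
the max absolute change), extracts clusters from attractor rows with the
lexicographic tie-break, and writes node<TAB>cluster lines.

Usage: mcl_oracle.py edges.tsv nodes.txt inflation pruning max_iter eps out.tsv
"""
import sys

import numpy as np


def main():
    edges_path, nodes_path, inflation, pruning, max_iter, eps, out_path = sys.argv[1:8]
    inflation = float(inflation)
    pruning = float(pruning)
    max_iter = int(max_iter)
    eps = float(eps)

    with open(nodes_path) as fh:
        nodes = [ln.strip() for ln in fh if ln.strip()]
    index = {n: i for i, n in enumerate(nodes)}
    n = len(nodes)

    A = np.zeros((n, n))
    with open(edges_path) as fh:
        header = fh.readline()
        for ln in fh:
            a, b, w = ln.rstrip("\n").split("\t")
            A[index[a], index[b]] = A[index[b], index[a]] = float(w)

    loop = A.max(axis=1)
    loop[loop == 0] = 1.0
    np.fill_diagonal(A, loop)
    M = A / A.sum(axis=0, keepdims=True)

    for _ in range(max_iter):
        M2 = M @ M
        M2 = M2 ** inflation
        M2[M2 < pruning] = 0.0
        cs = M2.sum(axis=0)
        cs[cs == 0] = 1.0
        M2 = M2 / cs
        if np.abs(M2 - M).max() < eps:
            M = M2
            break
        M = M2

    tiny = 1e-6
    attractors = [i for i in range(n) if M[i, i] > tiny]
    if not attractors:
        attractors = list(range(n))
    cluster_of = [None] * n
    cluster_attr = []
    for a in sorted(attractors, key=lambda i: nodes[i]):
        members = [j for j in range(n) if M[a, j] > tiny]
        existing = sorted({cluster_of[j] for j in members
                           if cluster_of[j] is not None})
        if not existing:
            cid = len(cluster_attr)
            cluster_attr.append(nodes[a])
            for j in members:
                cluster_of[j] = cid
        else:
            cid = existing[0]
            for j in members:
                if cluster_of[j] is None:
                    cluster_of[j] = cid
    for i in range(n):
        if cluster_of[i] is None:
            cluster_attr.append(nodes[i])
            cluster_of[i] = len(cluster_attr) - 1

    with open(out_path, "w") as fh:
        for i, node in enumerate(nodes):
            fh.write(f"{node}\t{cluster_attr[cluster_of[i]]}\n")


if __name__ == "__main__":
    main()
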