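#!/usr/bin/env python
"""Independent caption-metric oracle.

Reads JSON from stdin: {"candidates": [str], "references": [[str]]} where
tokens are already normalized and space-joined.  Writes JSON to stdout:
{"bleu": [b1..b4], "rouge_l": r, "cider": c}.

Implements the published formulas directly: corpus-level BLEU with clipped
n-gram counts and brevity penalty (effective reference length = closest,
ties to the shorter); ROUGE-L as the LCS F-measure with beta = 1.2 (max
over references, mean over samples); CIDEr-D with TF-IDF n-gram vectors
(n = 1..4), count clipping, Gaussian length penalty sigma = 6, scaled by
10.
"""
import sys, json, math
from collections import Counter


def ngrams(toks, n):
    return Counter(tuple(toks[i:i + n]) for i in range(len(toks) - n + 1))


def bleu(cands, refs, max_n=4):
    correct = [0.0] * max_n
    total = [0.0] * max_n
    clen = 0
    rlen = 0
    for c, rs in zip(cands, refs):
        clen += len(c)
        rlen += min((abs(len(r) - len(c)), len(r)) for r in rs)[1]
        for n in range(1, max_n + 1):
            cc = ngrams(c, n)
            total[n - 1] += sum(cc.values())
            best = Counter()
            for r in rs:
                rc = ngrams(r, n)
                for g in cc:
                    best[g] = max(best[g], rc.get(g, 0))
            correct[n - 1] += sum(min(cc[g], best[g]) for g in cc)
    p = [correct[i] / total[i] if total[i] > 0 else 0.0
         for i in range(max_n)]
    bp = 1.0 if clen > rlen else math.exp(1 - rlen / max(clen, 1))
    out = []
    for n in range(1, max_n + 1):
        if any(pi == 0 for pi in p[:n]):
            out.append(0.0)
        else:
            out.append(bp * math.exp(sum(math.log(pi)
                                         for pi in p[:n]) / n))
    return out


def lcs(a, b):
    prev = [0] * (len(b) + 1)
    for x in a:
        cur = [0] * (len(b) + 1)
        for j, y in enumerate(b):
            cur[j + 1] = prev[j] + 1 if x == y else max(cur[j],
                                                        prev[j + 1])
        prev = cur
    return prev[-1]


def rouge_l(cands, refs, beta=1.2):
    scores = []
    for c, rs in zip(cands, refs):
        best = 0.0
        for r in rs:
            l = lcs(c, r)
            if l == 0:
                continue
            prec = l / len(c)
            rec = l / len(r)
            best = max(best, (1 + beta ** 2) * prec * rec /
                       (rec + beta ** 2 * prec))
        scores.append(best)
    return sum(scores) / len(scores)


def cider(cands, refs, sigma=6.0, max_n=4):
    N = len(cands)
    df = [Counter() for _ in range(max_n)]
    for rs in refs:
        for n in range(max_n):
            seen = set()
            for r in rs:
                seen.update(ngrams(r, n + 1).keys())
            for g in seen:
                df[n][g] += 1
    logN = math.log(N)

    def vec(toks):
        out = []
        for n in range(max_n):
            cc = ngrams(toks, n + 1)
            out.append({g: cnt * (logN - math.log(max(df[n].get(g, 0), 1)))
                        for g, cnt in cc.items()})
        return out

    scores = []
    for c, rs in zip(cands, refs):
        vh = vec(c)
        nh = [math.sqrt(sum(v * v for v in d.values())) for d in vh]
        per_ref = []
        for r in rs:
            vr = vec(r)
            nr = [math.sqrt(sum(v * v for v in d.values())) for d in vr]
            delta = len(c) - len(r)
            vals = []
            for n in range(max_n):
                if nh[n] == 0 or nr[n] == 0:
                    vals.append(0.0)
                    continue
                s = sum(min(vh[n][g], vr[n][g]) * vr[n][g]
                        for g in vh[n] if g in vr[n])
                vals.append(s / (nh[n] * nr[n]))
            per_ref.append((sum(vals) / max_n) *
                           math.exp(-delta ** 2 / (2 * sigma ** 2)))
        scores.append(10.0 * sum(per_ref) / len(per_ref))
    return sum(scores) / len(scores)


def main():
    data = json.load(sys.stdin)
    cands = [c.split() for c in data["candidates"]]
    refs = [[r.split() for r in rs] for rs in data["references"]]
    json.dump({"bleu": bleu(cands, refs),
               "rouge_l": rouge_l(cands, refs),
               "cider": cider(cands, refs)}, sys.stdout)


if __name__ == "__main__":
    main()
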