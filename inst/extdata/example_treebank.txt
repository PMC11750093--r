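# Synthetic example treebank: one bracketed sentence per line, X-bar style,
# head-final VP, traces written as the leaf token t.
(S (NP (D the) (N boy)) (VP (V sleeps)))
(IP (NP (DP (D de)) (N student)) (VP (NP (DP (D een)) (N1 (N documentaire) (PP (P over) (NP (DP (D het)) (N heelal))))) (V gezien)))
(IP (NP (N wat)) (VP (NP t) (V at)))
(IP (NP (DP (D de)) (N hond)) (VP (PP (P in) (NP (DP (D de)) (N tuin))) (VP (V blaft))))
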