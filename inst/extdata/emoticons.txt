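# Text emoticons normalized to a single placeholder token during
# preprocessing.  One emoticon per line; matched against whole
# whitespace-delimited tokens.
:)
:-)
:))
:(
:-(
:((
:D
:-D
:P
:-P
:p
:-p
;)
;-)
;(
;-(
:/
:-/
:\
:o
:O
:|
:'(
:'-(
=)
=(
=D
=/
<3
</3
^_^
^-^
-_-
o_O
O_o
T_T
;_;
._.
:3
D:
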