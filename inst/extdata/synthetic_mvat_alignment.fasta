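>TurB_demo fictional demonstration sequence
MVRTLNNIRTLRAQARECTLETLEEMLEKLEVVVNERREEESAAAAEVEERTRKLQQYRE
M
>TurA_demo fictional demonstration sequence
MVRTLDNIRTLRAQAREITLETLAEMLDKLEVVVNERREEESQAAEVEERTRKLQEYRE-
M
>Pmr_demo fictional demonstration sequence
MSRTLNNIKILRAQVKECSLDELEAMSEKFQVVINERIEEEAQ--EVAERTRKLQDYREK
L
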