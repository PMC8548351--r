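>synthetic_chain
NPNGSPLLQQQERMQRQKQAKRFTW
>synth001
NPLGSPLLSQQERMGRQKQFKRFTW
>synth002
NPNGS-LLSQQERMQRQKQAKRFT-
>synth003
NPNGSPSLSQQEAMQVQKQ-KQFTW
>synth004
-PNGSILLQQQE-MQKQKQ-KRFTM
>synth005
NPNGLPLLQQQERMQRQKFAKRFTW
>synth006
GPNGSPLLQQ-ERMTRQKQAKRFTW
>synth007
NPNGSPLLSQIHREQRQKQFYQFTW
>synth008
N-NG-PSLSQQERMQRQAQAKRFTW
>synth009
G-NGSPLL-QQERMQRQKQSKRFTW
>synth010
GPNASPS-QQVPRGGRQKQAKRFVW
>synth011
NANG-PLLQQ--RMQRA-QA-RFSW
>synth012
NPNDSPLLQQQEREQRQKQAPMFTI
>synth013
LPNGSPLLQQQERGQRQKQAKRFTW
>synth014
NPNGSPLLQ-QERMQRVKQSKQFTW
>synth015
PPNGSPLLQQQERMQRQ-QAKAFTM
>synth016
NPNGSPLLQQ-ERMQRQKQA-RFTL
>synth017
N-NGSSSLQQQ-RMQRQKQS-RFTM
>synth018
NPE-SPLLQQQERMQRKKPFK-FTW
>synth019
NP-GSSL-QQQERMQRQKFAKQF-W
>synth020
NPNGSPLLQQDERMQRQAQAFMFTW
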