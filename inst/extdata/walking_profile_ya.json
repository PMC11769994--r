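{"stride_period":1.12,"baseline":0.01,"onset":{"ILIA":0.383466954195727,"GMAXI":1.11999999888,"HAM":0.832008798512735,"RECTF":0,"VASTI":1.11999999888,"BFES":0.870388507709716,"GAMS":0,"SOLEU":0.374650963997806,"TIBAN":0.826115145616314},"offset":{"ILIA":1.08446236555583,"GMAXI":1.11999999888,"HAM":0.343664714684649,"RECTF":1.11999999888,"VASTI":0.683160243520797,"BFES":0.0904913395535429,"GAMS":0.744750272406789,"SOLEU":0.742699789944329,"TIBAN":0.187668473689887},"amplitude":{"ILIA":0.01,"GMAXI":0.0719388467299804,"HAM":0.283966612283399,"RECTF":0.181153937255022,"VASTI":0.485166574091937,"BFES":0.511926756914909,"GAMS":1,"SOLEU":0.6230602778303,"TIBAN":0.932954675707014}}
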