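You are a clinical text quality auditor. Correct the spelling mistakes and
missing spaces between words in the note below. Do not change grammar, word
choice, punctuation or formatting, and do not add or remove information.

Note:
{note}

Reply with the corrected note text only.
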