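{"note_id": "sample-01", "text": "Spot on lip is gone. Overall doing well. Has a runny nose it no fever or any other symptoms.", "authored_at": "2020-11-05T09:15:00", "modality": "voice_transcript"}
{"note_id": "sample-02", "text": "Alex oxygen was still hanging out around 80 today. Blood sugar is 127.", "authored_at": "2020-11-05T20:40:00", "modality": "voice_transcript"}
{"note_id": "sample-03", "text": "Gave Alex 2 Benadryl at 6:00 am. Alex does not take his medicine after lunch.", "authored_at": "2020-11-06T07:05:00", "modality": "voice_transcript"}
{"note_id": "sample-04", "text": "Yesterday we started gabapentin at a rate of 2.6 ml that will continue for one week, then we will switch rate to 2 ml over the course of another week, then 1.6 ml for another week with final rate at 0.6 ml.", "authored_at": "2020-11-07T19:30:00", "modality": "voice_transcript"}
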